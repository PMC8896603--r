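# Independent brute-force oracles used to verify the optimized implementations.

# Direct evaluation of the Scholz-Stephens midrank k-sample AD statistic,
# written as plain per-distinct-value loops over the discrete formula.
ad_naive <- function(samples, standardized = TRUE) {
  pooled <- unlist(samples)
  nn <- length(pooled)
  k <- length(samples)
  z <- sort(unique(pooled))
  a2 <- 0
  for (i in seq_len(k)) {
    si <- 0
    ni <- length(samples[[i]])
    for (j in seq_along(z)) {
      lj <- sum(pooled == z[j])
      fij <- sum(samples[[i]] == z[j])
      maij <- sum(samples[[i]] < z[j]) + fij / 2
      baj <- sum(pooled < z[j]) + lj / 2
      denom <- baj * (nn - baj) - nn * lj / 4
      si <- si + (lj / nn) * (nn * maij - ni * baj)^2 / denom
    }
    a2 <- a2 + si / ni
  }
  a2 <- (nn - 1) / nn * a2
  if (!standardized) return(a2)
  hh <- sum(1 / lengths(samples))
  h <- sum(1 / seq_len(nn - 1))
  g <- 0
  for (i in seq_len(nn - 2)) {
    for (j in seq(i + 1, nn - 1)) g <- g + 1 / ((nn - i) * j)
  }
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * hh
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * hh - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * hh + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  var_a2 <- (a * nn^3 + b * nn^2 + cc * nn + d) / ((nn - 1) * (nn - 2) * (nn - 3))
  (a2 - (k - 1)) / sqrt(var_a2)
}

# Exhaustive edge scan for the Otsu threshold: for every interior bin edge,
# compute the class weights and means straight from the binned counts.
otsu_naive <- function(values, nbins = 256) {
  breaks <- seq(min(values), max(values), length.out = nbins + 1)
  h <- hist(values, breaks = breaks, plot = FALSE)
  p <- h$counts / length(values)
  mids <- h$mids
  best <- -Inf
  best_edge <- NA_real_
  for (t in seq_len(nbins - 1)) {
    w0 <- sum(p[1:t])
    w1 <- sum(p[(t + 1):nbins])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * mids[1:t]) / w0
    mu1 <- sum(p[(t + 1):nbins] * mids[(t + 1):nbins]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-15) {
      best <- bcv
      best_edge <- breaks[t + 1]
    }
  }
  best_edge
}

# Slow alternating solver for the ComBat EB fixed point with fixed
# hyperparameters, run to a much tighter tolerance than the implementation.
combat_eb_naive <- function(z, slide_id, gamma_hat, delta2_init, hyper,
                            tol = 1e-12, max_iter = 10000) {
  slides <- names(gamma_hat)
  g <- gamma_hat
  d2 <- delta2_init
  for (it in seq_len(max_iter)) {
    g_old <- g
    d2_old <- d2
    for (s in slides) {
      zi <- z[slide_id == s]
      u <- length(zi)
      d2[s] <- (hyper$beta_bar + 0.5 * sum((zi - g[s])^2)) /
        (u / 2 + hyper$omega_bar - 1)
      g[s] <- (u * hyper$tau2_bar * gamma_hat[s] + d2[s] * hyper$gamma_bar) /
        (u * hyper$tau2_bar + d2[s])
    }
    if (max(abs(c(g - g_old, d2 - d2_old))) < tol) break
  }
  list(gamma_star = g, delta2_star = d2)
}

# Small deterministic two-channel table builder for unit tests.
toy_table <- function(values_by_slide, channel = "ch", scale = "raw") {
  df <- data.frame(
    slide_id = rep(names(values_by_slide), lengths(values_by_slide)),
    v = unlist(values_by_slide, use.names = FALSE))
  names(df)[2] <- channel
  cell_table(df, channels = channel, scale_tag = scale, validate = FALSE)
}
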