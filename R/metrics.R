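#' k-sample Anderson-Darling alignment statistic
#'
#' Measures the evidence that per-slide intensity samples are drawn from
#' different parent distributions; larger values mean more separated
#' distributions, so good normalization drives it down. Uses the
#' Scholz-Stephens rank statistic in its midrank (tie-corrected) form, which
#' matters here because raw median-pixel intensities are integers with heavy
#' ties. The default is the standardized version
#' \eqn{T = (A^2_{akN} - (k-1))/\sigma_N}; `statistic = "raw"` returns
#' \eqn{A^2_{akN}} itself.
#'
#' @param samples List of numeric vectors, one per slide (k >= 2).
#' @param statistic `"standardized"` (default) or `"raw"`.
#' @return The statistic (a single number).
#' @export
#' @examples
#' ad_ksample(list(rnorm(100), rnorm(100, 2)))
ad_ksample <- function(samples, statistic = c("standardized", "raw")) {
  statistic <- match.arg(statistic)
  k <- length(samples)
  if (k < 2) abort("need at least 2 samples")
  n_i <- lengths(samples)
  if (any(n_i == 0)) abort("empty sample")
  if (any(n_i < 5)) warn("samples with fewer than 5 values; statistic unstable")
  pooled <- unlist(samples, use.names = FALSE)
  nn <- length(pooled)
  zstar <- sort(unique(pooled))
  big_l <- length(zstar)
  if (big_l < 2) abort("all pooled values identical; statistic undefined")
  l_j <- as.vector(table(match(pooled, zstar)))
  b_cum <- cumsum(l_j)
  b_aj <- b_cum - l_j / 2
  denom <- b_aj * (nn - b_aj) - nn * l_j / 4
  inner_sum <- 0
  for (i in seq_len(k)) {
    f_ij <- tabulate(match(samples[[i]], zstar), nbins = big_l)
    m_aij <- cumsum(f_ij) - f_ij / 2
    term <- (l_j / nn) * (nn * m_aij - n_i[i] * b_aj)^2 / denom
    inner_sum <- inner_sum + sum(term) / n_i[i]
  }
  a2 <- (nn - 1) / nn * inner_sum
  if (statistic == "raw") return(a2)
  (a2 - (k - 1)) / sqrt(ad_variance(k, n_i))
}

# Scholz-Stephens variance of A2kN under the null, used to standardize
ad_variance <- function(k, n_i) {
  nn <- sum(n_i)
  hh <- sum(1 / n_i)
  h <- sum(1 / seq_len(nn - 1))
  # g = sum_{i=1}^{N-2} (1/(N-i)) * (h_{N-1} - h_i), computed in O(N)
  hcum <- cumsum(1 / seq_len(nn - 1))
  i_idx <- seq_len(nn - 2)
  g <- sum((hcum[nn - 1] - hcum[i_idx]) / (nn - i_idx))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * hh
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * hh - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * hh + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  (a * nn^3 + b * nn^2 + cc * nn + d) / ((nn - 1) * (nn - 2) * (nn - 3))
}

#' Otsu threshold of an intensity sample
#'
#' Bins the values into `nbins` equal-width histogram bins over their range
#' and returns the bin edge maximizing the between-class variance
#' \eqn{\omega_0\omega_1(\mu_0 - \mu_1)^2} of the split; cells above the
#' threshold are called marker-positive. Ties are broken by the smallest
#' edge.
#'
#' @param values Intensities (>= 2 distinct values).
#' @param nbins Number of histogram bins.
#' @return The threshold (a bin edge).
#' @export
otsu_threshold <- function(values, nbins = 256) {
  rng <- range(values)
  if (rng[1] == rng[2]) {
    abort("all values identical; Otsu threshold undefined",
          class = "slidenorm_degenerate_threshold_error")
  }
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  p <- h$counts / length(values)
  mids <- h$mids
  cp <- cumsum(p)[-nbins]           # class-0 weight at each interior edge
  cm <- cumsum(p * mids)[-nbins]    # class-0 unnormalized mean
  mu_all <- sum(p * mids)
  w0 <- cp; w1 <- 1 - cp
  bcv <- ifelse(w0 > 0 & w1 > 0,
                (mu_all * w0 - cm)^2 / (w0 * w1), -Inf)
  breaks[which.max(bcv) + 1]
}

#' Otsu threshold discordance across slides
#'
#' Quantifies how differently marker-positive calls come out when thresholds
#' are set per slide versus globally. With \eqn{o_{ic}} the slide-specific
#' and \eqn{o_c} the pooled global Otsu threshold, each slide's score is the
#' proportion of its cells whose positive/negative call flips between the
#' two thresholds; the summary is the mean score across the N slides. Lower
#' is better. A slide whose threshold is degenerate (all values identical)
#' inherits the global calls and scores 0, with a warning.
#'
#' @param x A `cell_tbl`.
#' @param channel Channel name.
#' @param nbins Histogram bins for the thresholds.
#' @return A list with `scores` (tibble: `slide_id`, `threshold`, `score`),
#'   `global_threshold`, and `mean` (mean score across slides).
#' @export
otsu_discordance <- function(x, channel, nbins = 256) {
  if (dplyr::n_distinct(x$slide_id) < 2) abort("need >= 2 slides")
  y <- x[[channel]]
  o_c <- otsu_threshold(y, nbins)
  ys <- split(y, x$slide_id)
  rows <- purrr::imap(ys, function(v, sl) {
    o_ic <- tryCatch(otsu_threshold(v, nbins), slidenorm_degenerate_threshold_error =
      function(e) {
        warn(sprintf("slide '%s': degenerate threshold; scoring against global calls", sl))
        NA_real_
      })
    score <- if (is.na(o_ic)) 0 else mean(abs((v > o_ic) - (v > o_c)))
    tibble(slide_id = sl, threshold = o_ic, score = score)
  })
  scores <- bind_rows(rows)
  list(scores = scores, global_threshold = o_c, mean = mean(scores$score))
}

#' Marker-positive accuracy against manual labels
#'
#' Calls cells marker-positive with the global (all-slides pooled) Otsu
#' threshold and returns the proportion of cells whose call matches the
#' manual positive/negative label.
#'
#' @param x A `cell_tbl`.
#' @param channel Channel name.
#' @param labels Binary manual labels (0/1 or logical), one per cell, or
#'   `NULL` to use the table's `manual_pos_<channel>` column.
#' @param nbins Histogram bins for the threshold.
#' @return Accuracy in \[0, 1\].
#' @export
marker_positive_accuracy <- function(x, channel, labels = NULL, nbins = 256) {
  if (is.null(labels)) {
    col <- paste0("manual_pos_", channel)
    if (!col %in% names(x)) abort(sprintf("no manual labels for channel '%s'", channel))
    labels <- x[[col]]
  }
  if (length(labels) != nrow(x)) abort("labels length must match cell count")
  if (all(is.na(labels))) abort("no labeled cells")
  o_c <- otsu_threshold(x[[channel]], nbins)
  calls <- x[[channel]] > o_c
  mean(calls == as.logical(labels), na.rm = TRUE)
}

#' Slide-level variance proportion from a random-intercept model
#'
#' Fits \eqn{Y = \mu + b_i + \varepsilon}, \eqn{b_i \sim N(0,
#' \sigma^2_{slide})}, \eqn{\varepsilon \sim N(0, \sigma^2_{res})} by REML
#' and returns the intraclass correlation
#' \eqn{\sigma^2_{slide} / (\sigma^2_{slide} + \sigma^2_{res})} — the share
#' of intensity variance attributable to the slide. Boundary estimates of 0
#' are reported as 0. If the mixed-model fit fails, a one-way ANOVA
#' method-of-moments estimator is used with a warning.
#'
#' @param values One channel's intensities.
#' @param slide_ids Slide identifier per value.
#' @return Proportion in \[0, 1\].
#' @export
variance_proportion <- function(values, slide_ids) {
  slide_ids <- as.character(slide_ids)
  if (dplyr::n_distinct(slide_ids) < 2) abort("need >= 2 slides")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 1 + (1 | s), data = data.frame(y = values, s = slide_ids),
                 REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_slide <- vc$vcov[vc$grp == "s"]
    v_res <- vc$vcov[vc$grp == "Residual"]
    return(v_slide / (v_slide + v_res))
  }
  warn("mixed-model fit failed; using one-way ANOVA method-of-moments estimator")
  anova_icc(values, slide_ids)
}

anova_icc <- function(values, slide_ids) {
  n_i <- tapply(values, slide_ids, length)
  m_i <- tapply(values, slide_ids, mean)
  k <- length(n_i)
  nn <- sum(n_i)
  gm <- mean(values)
  msb <- sum(n_i * (m_i - gm)^2) / (k - 1)
  msw <- sum((values - m_i[slide_ids])^2) / (nn - k)
  n0 <- (nn - sum(n_i^2) / nn) / (k - 1)
  v_slide <- max(0, (msb - msw) / n0)
  v_slide / (v_slide + msw)
}

#' Adjusted Rand index of two partitions
#'
#' Hubert-Arabie chance-corrected agreement between two labelings of the
#' same cells, computed from the contingency table. 1 means identical
#' partitions (up to label names), values near 0 mean chance-level
#' agreement.
#'
#' @param labels_a,labels_b Two labelings of equal length (>= 2).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("labelings must have equal length")
  n <- length(labels_a)
  if (n < 2) abort("need at least 2 items")
  tab <- table(labels_a, labels_b)
  choose2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}
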