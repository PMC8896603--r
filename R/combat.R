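#' Standardize one channel for ComBat fitting
#'
#' Implements the location-scale standardization that precedes the
#' empirical-Bayes step. For channel \eqn{c}: the grand mean
#' \eqn{\hat\alpha_c} is the cell-weighted mean over all slides; the pooled
#' residual scale is \eqn{\hat\sigma_c^2 = N^{-1}\sum (Y - \bar Y_{slide})^2}
#' (residuals after removing slide means); the standardized data are
#' \eqn{Z = (Y - \hat\alpha_c)/\hat\sigma_c}. Per-slide means of \eqn{Z} are
#' the naive mean batch effects \eqn{\hat\gamma_{ic}} and per-slide sample
#' variances of \eqn{Z} the naive variance effects \eqn{\hat\delta^2_{ic}},
#' so that \eqn{Z \mid i \sim N(\gamma_{ic}, \delta^2_{ic})} under the model.
#'
#' @param x A `cell_tbl`.
#' @param channel Channel name.
#' @return A list with `z` (standardized values, in row order), `alpha`,
#'   `sigma`, and `slide_stats` (tibble: `slide_id`, `n_cells`, `gamma_hat`,
#'   `delta2_hat`).
#' @export
combat_standardize <- function(x, channel) {
  if (!channel %in% channels(x)) abort(sprintf("unknown channel '%s'", channel))
  y <- x[[channel]]
  slide <- x$slide_id
  if (dplyr::n_distinct(slide) < 2) {
    abort("ComBat requires at least 2 slides", class = "slidenorm_batch_design_error")
  }
  alpha <- mean(y)
  slide_mean <- tapply(y, slide, mean)
  sigma2 <- mean((y - slide_mean[slide])^2)
  if (sigma2 <= 0) {
    abort(sprintf("channel '%s' is constant within slides; cannot standardize", channel),
          class = "slidenorm_degenerate_channel_error")
  }
  sigma <- sqrt(sigma2)
  z <- (y - alpha) / sigma
  zs <- split(z, slide)
  stats <- tibble(
    slide_id = names(zs),
    n_cells = unname(vapply(zs, length, integer(1))),
    gamma_hat = unname(vapply(zs, mean, numeric(1))),
    delta2_hat = unname(vapply(zs, function(v) if (length(v) > 1) stats::var(v) else 1,
                               numeric(1)))
  )
  list(z = z, alpha = alpha, sigma = sigma, slide_stats = stats)
}

#' Method-of-moments hyperparameters for the ComBat priors
#'
#' The slide mean effects are modelled as \eqn{\gamma_{ic} \sim
#' N(\bar\gamma_c, \bar\tau^2_c)} and the variance effects as
#' \eqn{\delta^2_{ic} \sim IG(\bar\omega_c, \bar\beta_c)}. Moment matching
#' gives \eqn{\bar\gamma_c} and \eqn{\bar\tau^2_c} as the across-slide mean
#' and sample variance of \eqn{\hat\gamma_{ic}}, and with \eqn{m, v} the
#' across-slide mean and variance of \eqn{\hat\delta^2_{ic}},
#' \eqn{\bar\omega_c = m^2/v + 2} and \eqn{\bar\beta_c = m(\bar\omega_c - 1)}
#' (so the implied prior mean \eqn{\bar\beta_c/(\bar\omega_c-1)} equals
#' \eqn{m}). When \eqn{v = 0} the inverse-gamma moments are undefined; the
#' prior is then flagged non-informative and set flat
#' (\eqn{\bar\omega_c = 1, \bar\beta_c = 0}), so the variance update reduces
#' to the within-slide mean square.
#'
#' @param gamma_hat Per-slide mean effects on the standardized scale.
#' @param delta2_hat Per-slide variance effects on the standardized scale.
#' @return List with `gamma_bar`, `tau2_bar`, `omega_bar`, `beta_bar`, and
#'   `informative_variance_prior` (FALSE when the flat fallback was used).
#' @export
combat_mom_hyperparams <- function(gamma_hat, delta2_hat) {
  if (length(gamma_hat) < 2) abort("need >= 2 slides for method-of-moments hyperparameters")
  gamma_bar <- mean(gamma_hat)
  tau2_bar <- stats::var(gamma_hat)
  m <- mean(delta2_hat)
  v <- stats::var(delta2_hat)
  if (v <= 0) {
    warn("across-slide variance of delta2_hat is zero; using a flat (non-informative) variance prior",
         class = "slidenorm_noninformative_prior_warning")
    list(gamma_bar = gamma_bar, tau2_bar = tau2_bar,
         omega_bar = 1, beta_bar = 0, informative_variance_prior = FALSE)
  } else {
    omega_bar <- m^2 / v + 2
    list(gamma_bar = gamma_bar, tau2_bar = tau2_bar,
         omega_bar = omega_bar, beta_bar = m * (omega_bar - 1),
         informative_variance_prior = TRUE)
  }
}

#' Empirical-Bayes fixed-point iteration for slide effects
#'
#' Given fixed hyperparameters, alternates the two posterior-mean updates
#' until the largest absolute parameter change falls below `tol`:
#' \deqn{\delta^{2*}_{ic} = \frac{\bar\beta_c + \tfrac12 \sum_u (Z_{ic}(u) -
#'   \gamma^*_{ic})^2}{U_{ic}/2 + \bar\omega_c - 1}, \qquad
#'   \gamma^*_{ic} = \frac{U_{ic}\bar\tau^2_c\hat\gamma_{ic} +
#'   \delta^{2*}_{ic}\bar\gamma_c}{U_{ic}\bar\tau^2_c + \delta^{2*}_{ic}}.}
#' The mean update shrinks each naive slide effect toward the prior mean
#' \eqn{\bar\gamma_c}, with less shrinkage for better-sampled slides.
#'
#' @param z Standardized values.
#' @param slide_id Slide identifier per value.
#' @param gamma_hat Named per-slide naive mean effects (initial
#'   \eqn{\gamma^*}).
#' @param delta2_init Named per-slide initial variance effects.
#' @param hyper Output of [combat_mom_hyperparams()].
#' @param tol Convergence tolerance on the max absolute parameter change.
#' @param max_iter Iteration cap; non-convergence returns the current values
#'   with `converged = FALSE` and a warning.
#' @return List with named vectors `gamma_star`, `delta2_star`, plus
#'   `iterations` and `converged`.
#' @export
combat_eb_iterate <- function(z, slide_id, gamma_hat, delta2_init, hyper,
                              tol = 1e-5, max_iter = 100) {
  zs <- split(z, slide_id)
  zs <- zs[names(gamma_hat)]
  u <- vapply(zs, length, numeric(1))
  g <- gamma_hat
  d2 <- delta2_init
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    ss <- vapply(seq_along(zs), function(i) sum((zs[[i]] - g[i])^2), numeric(1))
    d2_new <- (hyper$beta_bar + 0.5 * ss) / (u / 2 + hyper$omega_bar - 1)
    g_new <- (u * hyper$tau2_bar * g_naive(gamma_hat) + d2_new * hyper$gamma_bar) /
      (u * hyper$tau2_bar + d2_new)
    delta <- max(abs(c(g_new - g, d2_new - d2)))
    g <- g_new; d2 <- d2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("EB iteration did not converge in %d iterations", max_iter),
         class = "slidenorm_convergence_warning")
  }
  list(gamma_star = g, delta2_star = d2, iterations = it, converged = converged)
}

# the naive estimate stays fixed in the gamma update; alias for readability
g_naive <- function(gamma_hat) gamma_hat

#' Adjust standardized values with fitted slide effects
#'
#' Removes the EB slide effects and rescales back to the original channel
#' scale: \eqn{Y^*_{ic}(u) = (\hat\sigma_c / \hat\delta^*_{ic})
#' (Z_{ic}(u) - \gamma^*_{ic}) + \hat\alpha_c} with
#' \eqn{\hat\delta^*_{ic} = \sqrt{\delta^{2*}_{ic}}}. With
#' \eqn{\gamma^* = 0, \delta^* = 1} this inverts the standardization exactly.
#'
#' @param z Standardized values.
#' @param slide_id Slide identifier per value.
#' @param gamma_star,delta2_star Named per-slide EB estimates.
#' @param alpha,sigma Channel grand mean and pooled scale from
#'   [combat_standardize()].
#' @return Adjusted values on the original scale.
#' @export
combat_adjust <- function(z, slide_id, gamma_star, delta2_star, alpha, sigma) {
  if (any(delta2_star <= 0)) {
    abort("delta2_star must be positive", class = "slidenorm_internal_error")
  }
  dstar <- sqrt(delta2_star)[slide_id]
  unname((sigma / dstar) * (z - gamma_star[slide_id]) + alpha)
}

combat_fit_channel <- function(x, channel, tol = 1e-5, max_iter = 100) {
  std <- combat_standardize(x, channel)
  st <- std$slide_stats
  gamma_hat <- setNames(st$gamma_hat, st$slide_id)
  g <- gamma_hat
  d2 <- setNames(st$delta2_hat, st$slide_id)
  hyper <- NULL
  total_iter <- 0L
  converged <- FALSE
  noninf <- FALSE
  for (outer in seq_len(max_iter)) {
    # Re-estimating the variance prior from shrunken effects can drive their
    # spread to exactly zero (complete pooling); that is a fixed point, not a
    # degenerate input, so stop there instead of flipping to the flat prior.
    if (outer > 1 && stats::var(d2) <= 0) { converged <- TRUE; break }
    hyper <- withCallingHandlers(
      combat_mom_hyperparams(g, d2),
      slidenorm_noninformative_prior_warning = function(w) {
        noninf <<- TRUE
        invokeRestart("muffleWarning")
      })
    eb <- suppressWarnings(
      combat_eb_iterate(std$z, x$slide_id, gamma_hat, d2, hyper,
                        tol = tol, max_iter = max_iter))
    total_iter <- total_iter + eb$iterations
    delta <- max(abs(c(eb$gamma_star - g, eb$delta2_star - d2)))
    g <- eb$gamma_star
    d2 <- eb$delta2_star
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("ComBat outer loop for channel '%s' did not converge", channel),
         class = "slidenorm_convergence_warning")
  }
  list(channel = channel, alpha = std$alpha, sigma = std$sigma,
       slide_stats = st, gamma_star = g, delta2_star = d2,
       hyper = hyper, informative_variance_prior = !noninf,
       iterations = total_iter, converged = converged, z = std$z)
}

#' ComBat slide-effect normalization of a cell table
#'
#' Fits the empirical-Bayes location-scale model per channel — standardize,
#' method-of-moments hyperparameters, EB shrinkage of per-slide mean and
#' variance effects (hyperparameters re-estimated from the current shrunken
#' effects each outer pass, alternating until convergence) — and adjusts
#' every channel back to its original scale with the slide effects removed.
#' Zero intensities are retained as data throughout: a zero is a meaningful
#' low intensity, not a missing value.
#'
#' @param x A `cell_tbl` already carrying the desired transformation (or raw).
#' @param use_channels Channels to normalize; default all.
#' @param tol Convergence tolerance (max absolute parameter change).
#' @param max_iter Iteration cap per loop.
#' @param clip_nonnegative Clamp adjusted values at 0. The Gaussian model can
#'   produce negative adjusted intensities; the default keeps them.
#' @return A list with `table` (the adjusted `cell_tbl`) and `fit` (a
#'   `combat_fit`; see [tidy.combat_fit()] and [glance.combat_fit()]).
#' @export
#' @examples
#' sim <- simulate_table(sim_config(n_slides = 4, cells_per_slide = 100, seed = 1))
#' out <- combat_normalize(apply_transform(sim$table, "log10"))
#' glance(out$fit)
combat_normalize <- function(x, use_channels = NULL, tol = 1e-5, max_iter = 100,
                             clip_nonnegative = FALSE) {
  chs <- use_channels %||% channels(x)
  out <- as_tibble(x)
  fits <- purrr::map(set_names(chs), function(ch) {
    f <- combat_fit_channel(x, ch, tol = tol, max_iter = max_iter)
    ystar <- combat_adjust(f$z, x$slide_id, f$gamma_star, f$delta2_star,
                           f$alpha, f$sigma)
    if (clip_nonnegative) ystar <- pmax(ystar, 0)
    out[[ch]] <<- ystar
    f$z <- NULL
    f
  })
  tbl <- new_cell_tbl(out, channels = channels(x),
                      scale_tag = paste0(scale_tag(x), "+combat"))
  fit <- structure(list(channels = fits, tol = tol, max_iter = max_iter),
                   class = "combat_fit")
  list(table = tbl, fit = fit)
}

#' Tidy and summarize a ComBat fit
#'
#' `tidy()` returns one row per slide-channel with the naive and EB-shrunk
#' mean/variance effects; `glance()` returns one row per channel with the
#' grand mean, pooled scale, hyperparameters and convergence state.
#'
#' @param x A `combat_fit` from [combat_normalize()].
#' @param ... Unused.
#' @export
tidy.combat_fit <- function(x, ...) {
  purrr::imap(x$channels, function(f, ch) {
    f$slide_stats |>
      mutate(channel = ch,
             gamma_star = unname(f$gamma_star[.data$slide_id]),
             delta2_star = unname(f$delta2_star[.data$slide_id])) |>
      select("channel", dplyr::everything())
  }) |> bind_rows()
}

#' @rdname tidy.combat_fit
#' @export
glance.combat_fit <- function(x, ...) {
  purrr::imap(x$channels, function(f, ch) {
    tibble(channel = ch, alpha = f$alpha, sigma = f$sigma,
           gamma_bar = f$hyper$gamma_bar, tau2_bar = f$hyper$tau2_bar,
           omega_bar = f$hyper$omega_bar, beta_bar = f$hyper$beta_bar,
           informative_variance_prior = f$informative_variance_prior,
           iterations = f$iterations, converged = f$converged)
  }) |> bind_rows()
}

#' Serialize a ComBat fit to JSON
#'
#' @param fit A `combat_fit`.
#' @param path JSON output path.
#' @export
write_combat_fit <- function(fit, path) {
  per_ch <- purrr::map(fit$channels, function(f) {
    list(alpha = f$alpha, sigma = f$sigma, hyper = f$hyper[1:4],
         informative_variance_prior = f$informative_variance_prior,
         iterations = f$iterations, converged = f$converged,
         slides = as.list(tibble::column_to_rownames(
           as.data.frame(f$slide_stats |>
             mutate(gamma_star = unname(f$gamma_star[.data$slide_id]),
                    delta2_star = unname(f$delta2_star[.data$slide_id]))),
           "slide_id")))
  })
  jsonlite::write_json(per_ch, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
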