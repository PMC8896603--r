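#' Smooth per-slide intensity densities on a common grid
#'
#' Approximates the density of one slide-channel's intensities by binning the
#' values into equal-width histogram bins over the common grid range and
#' least-squares projecting the histogram density onto a 21-function cubic
#' B-spline basis (17 equally spaced interior knots). Fitted values are
#' clamped at zero (the unconstrained fit can dip negative) and renormalized
#' to integrate to 1 by the trapezoid rule.
#'
#' @param values One slide-channel's intensities.
#' @param grid Strictly increasing common evaluation grid spanning the pooled
#'   channel range.
#' @param nbins Histogram bins used before smoothing.
#' @param df Number of B-spline basis functions.
#' @return A list with `coef` (basis coefficients), `density` (fitted values
#'   on `grid`), and `grid`.
#' @export
estimate_density <- function(values, grid, nbins = 128, df = 21) {
  if (length(values) == 0) abort("no values to estimate a density from")
  a <- grid[1]; b <- grid[length(grid)]
  if (b <= a) abort("zero-width grid range")
  if (length(values) < 50) {
    warn("fewer than 50 values; density estimate will be noisy")
  }
  breaks <- seq(a, b, length.out = nbins + 1)
  v <- pmin(pmax(values, a), b)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  mids <- h$mids
  dens <- h$density
  basis_mid <- bspline_basis(mids, a, b, df)
  coef <- stats::lm.fit(basis_mid, dens)$coefficients
  coef[is.na(coef)] <- 0
  fit <- pmax(as.vector(bspline_basis(grid, a, b, df) %*% coef), 0)
  total <- trapz(grid, fit)
  if (total <= 0) abort("degenerate density fit (all mass clamped)")
  list(coef = unname(coef), density = fit / total, grid = grid)
}

bspline_basis <- function(x, a, b, df = 21, degree = 3) {
  n_interior <- df - degree - 1
  knots <- seq(a, b, length.out = n_interior + 2)[-c(1, n_interior + 2)]
  splines::bs(x, knots = knots, degree = degree, intercept = TRUE,
              Boundary.knots = c(a, b))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (head(y, -1) + y[-1]) / 2))

#' Build a DensitySet for one channel
#'
#' Fits all per-slide densities of a channel on a 512-point common grid over
#' the pooled range and computes the registration target: the pointwise
#' arithmetic mean of the slide densities.
#'
#' @param x A `cell_tbl`.
#' @param channel Channel name.
#' @param n_grid Number of grid points.
#' @param nbins,df Passed to [estimate_density()].
#' @return A list of class `density_set`: `channel`, `grid`, `slides` (named
#'   list of per-slide fits), `target` (mean density on the grid).
#' @export
density_set <- function(x, channel, n_grid = 512, nbins = 128, df = 21) {
  v <- x[[channel]]
  grid <- seq(min(v), max(v), length.out = n_grid)
  slides <- split(v, x$slide_id)
  fits <- purrr::map(slides, estimate_density, grid = grid, nbins = nbins, df = df)
  target <- rowMeans(vapply(fits, `[[`, numeric(n_grid), "density"))
  structure(list(channel = channel, grid = grid, slides = fits, target = target),
            class = "density_set")
}

warp_from_beta <- function(beta, grid) {
  a <- grid[1]; b <- grid[length(grid)]
  # 2-df linear B-spline exponent: hat functions h1 = (b-y)/(b-a), h2 = (y-a)/(b-a)
  h2 <- (grid - a) / (b - a)
  w <- exp(beta[1] * (1 - h2) + beta[2] * h2)
  W <- cumtrapz(grid, w)
  a + (b - a) * W / W[length(W)]
}

#' Fit a monotone warping function aligning a slide density to the target
#'
#' The warp family is \eqn{\phi(x) = C_0 + C_1 \int_a^x \exp\{\beta_1 h_1(y)
#' + \beta_2 h_2(y)\}\,dy} with \eqn{h_1, h_2} the two hat functions of a
#' linear B-spline basis on \eqn{[a,b]} (2 degrees of freedom); the endpoint
#' constraints \eqn{\phi(a)=a,\ \phi(b)=b} determine \eqn{C_0, C_1}, and the
#' positive integrand makes \eqn{\phi} strictly increasing. The coefficients
#' minimize the trapezoid quadrature of
#' \eqn{\int \| f_{ic}(\phi(y)) - \bar f(y) \|^2 dy} over the grid, starting
#' from the identity (\eqn{\beta_1=\beta_2=0}) with box bounds [-5, 5].
#'
#' @param slide_density A per-slide entry of a [density_set()] (list with
#'   `density` on the grid).
#' @param target Target density values on the same grid.
#' @param grid The common grid.
#' @return A list of class `warp_fn`: `beta`, `grid`, `phi` (warp values on
#'   the grid), `domain`, `objective`, and `converged`.
#' @export
fit_warp <- function(slide_density, target, grid) {
  f_slide <- slide_density$density
  obj <- function(beta) {
    phi <- warp_from_beta(beta, grid)
    f_at_phi <- stats::approx(grid, f_slide, xout = phi, rule = 2)$y
    trapz(grid, (f_at_phi - target)^2)
  }
  res <- tryCatch(
    stats::optim(c(0, 0), obj, method = "L-BFGS-B", lower = -5, upper = 5),
    error = function(e) NULL)
  if (is.null(res)) {
    warn("warp optimization failed; returning identity warp")
    res <- list(par = c(0, 0), value = obj(c(0, 0)), convergence = 1L)
  }
  phi <- warp_from_beta(res$par, grid)
  structure(list(beta = res$par, grid = grid, phi = phi,
                 domain = c(grid[1], grid[length(grid)]),
                 objective = res$value, converged = res$convergence == 0),
            class = "warp_fn")
}

#' Map intensities through a fitted warp
#'
#' Applies \eqn{Y^* = \phi(Y)} by monotone linear interpolation of the
#' tabulated warp. Values outside the warp domain are clamped to the
#' endpoints (counted and warned about); within-slide rank order is
#' preserved because \eqn{\phi} is strictly increasing.
#'
#' @param values Intensities to normalize.
#' @param warp A `warp_fn`.
#' @param direction `"inverse"` (default) transports observations through
#'   the numerically inverted warp \eqn{\phi^{-1}}: since the objective
#'   aligns \eqn{f_{ic}\circ\phi} with the target, a slide shifted right of
#'   the average gets \eqn{\phi(y) = y + s}, and observations must move by
#'   \eqn{-s} (i.e. through \eqn{\phi^{-1}}) for their density to land on
#'   the target. `"as_fitted"` applies \eqn{\phi} itself.
#' @return Normalized intensities.
#' @export
apply_warp <- function(values, warp, direction = c("inverse", "as_fitted")) {
  direction <- match.arg(direction)
  a <- warp$domain[1]; b <- warp$domain[2]
  n_out <- sum(values < a | values > b)
  if (n_out > 0) {
    warn(sprintf("%d value(s) outside warp domain [%g, %g]; clamped", n_out, a, b))
  }
  v <- pmin(pmax(values, a), b)
  if (direction == "as_fitted") {
    stats::approx(warp$grid, warp$phi, xout = v, rule = 2)$y
  } else {
    stats::approx(warp$phi, warp$grid, xout = v, rule = 2, ties = "ordered")$y
  }
}

#' Density-registration normalization of a cell table
#'
#' For each channel: smooths every slide's intensity histogram into a density
#' on a common grid, computes the cross-slide average density, fits one
#' monotone warping function per slide aligning its density to the average,
#' and maps each cell's intensity through its slide's warp. Reports the
#' k-sample Anderson-Darling alignment statistic before and after as a
#' diagnostic.
#'
#' @inheritParams combat_normalize
#' @param direction Warp transport direction; see [apply_warp()].
#' @param n_grid,nbins,df Density-estimation resolution; see
#'   [density_set()].
#' @return A list with `table` (warped `cell_tbl`) and `registration` (per
#'   channel: the `density_set`, the list of `warp_fn`s, and the
#'   before/after AD statistics).
#' @export
#' @examples
#' sim <- simulate_table(sim_config(n_slides = 3, cells_per_slide = 200, seed = 2))
#' out <- register_normalize(apply_transform(sim$table, "log10"),
#'                           use_channels = "cd3")
#' out$registration$cd3$ad_before >= out$registration$cd3$ad_after
register_normalize <- function(x, use_channels = NULL,
                               direction = c("inverse", "as_fitted"),
                               n_grid = 512, nbins = 128, df = 21) {
  direction <- match.arg(direction)
  chs <- use_channels %||% channels(x)
  out <- as_tibble(x)
  reg <- purrr::map(set_names(chs), function(ch) {
    ds <- density_set(x, ch, n_grid = n_grid, nbins = nbins, df = df)
    warps <- purrr::map(ds$slides, fit_warp, target = ds$target, grid = ds$grid)
    before <- split(x[[ch]], x$slide_id)
    new_vals <- x[[ch]]
    for (sl in names(warps)) {
      idx <- x$slide_id == sl
      new_vals[idx] <- apply_warp(x[[ch]][idx], warps[[sl]], direction = direction)
    }
    out[[ch]] <<- new_vals
    list(densities = ds, warps = warps,
         ad_before = ad_ksample(before),
         ad_after = ad_ksample(split(new_vals, x$slide_id)))
  })
  tbl <- new_cell_tbl(out, channels = channels(x),
                      scale_tag = paste0(scale_tag(x), "+registration"))
  list(table = tbl, registration = reg)
}

#' Export warp tables as CSV
#'
#' Writes one two-column CSV (`y`, `phi`) per slide for a channel's fitted
#' warps, so the same normalization can be applied downstream (e.g. at the
#' pixel level) or audited.
#'
#' @param warps Named list of `warp_fn`s (one per slide).
#' @param dir Output directory.
#' @param channel Channel name used in the file names.
#' @return The written paths, invisibly.
#' @export
write_warp_tables <- function(warps, dir, channel) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(warps, function(w, sl) {
    p <- file.path(dir, sprintf("warp_%s_%s.csv", channel, sl))
    readr::write_csv(tibble(y = w$grid, phi = w$phi), p, progress = FALSE)
    p
  })
  invisible(paths)
}
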