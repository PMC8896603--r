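#' Intensity-scale transformations
#'
#' Three strictly monotone rescalings of raw median cell intensities, applied
#' per slide and channel before (or instead of) normalization:
#'
#' * `transform_log10()`: \eqn{\log_{10}(y + 1)} — the +1 offset keeps zero
#'   intensities finite since raw values are integer-valued.
#' * `transform_mean_divide()`: \eqn{y / \mu_{ic}} where \eqn{\mu_{ic}} is the
#'   slide mean of the raw channel; forces every slide mean to 1 exactly.
#' * `transform_mean_divide_log10()`: \eqn{\log_{10}(y/\mu_{ic} + 1/2)} —
#'   values above half the slide mean become positive, values below negative,
#'   with lower bound \eqn{\log_{10}(1/2)} at \eqn{y = 0}.
#'
#' @param y Non-negative intensity values.
#' @param mu Slide-channel mean \eqn{\mu_{ic}} of the raw values; must be > 0.
#' @return Transformed values, same length as `y`.
#' @export
transform_log10 <- function(y) {
  if (any(y < 0)) abort("log10 transform requires y >= 0")
  log10(y + 1)
}

#' @rdname transform_log10
#' @export
transform_mean_divide <- function(y, mu) {
  check_mu(mu)
  y / mu
}

#' @rdname transform_log10
#' @export
transform_mean_divide_log10 <- function(y, mu) {
  check_mu(mu)
  log10(y / mu + 0.5)
}

check_mu <- function(mu) {
  if (any(mu <= 0)) {
    abort("slide-channel mean must be > 0 (degenerate all-zero slide)",
          class = "slidenorm_degenerate_slide_error")
  }
  invisible(mu)
}

transform_kinds <- c("none", "log10", "mean_divide", "mean_divide_log10")

#' Apply a scale transformation to a cell table
#'
#' Transforms every channel of a raw-scale table by one of the three supported
#' rescalings (or `"none"`). Slide-channel means \eqn{\mu_{ic}} are always
#' computed from the raw values at application time and recorded in the
#' returned table's `transform_spec` attribute, so the identical mapping can
#' be reapplied to held-out cells from the same slides and audited later.
#'
#' @param x A `cell_tbl` on the raw scale.
#' @param kind One of `"none"`, `"log10"`, `"mean_divide"`,
#'   `"mean_divide_log10"`.
#' @return A `cell_tbl` with transformed channels, `scale_tag` set to `kind`,
#'   and a `transform_spec` attribute (retrieve with [transform_spec()]).
#' @export
#' @examples
#' tbl <- cell_table(data.frame(slide_id = c("a", "a", "b", "b"),
#'                              cd3 = c(2, 4, 3, 9)))
#' out <- apply_transform(tbl, "mean_divide")
#' slide_summary(out, "cd3")  # per-slide means are exactly 1
apply_transform <- function(x, kind = c("none", "log10", "mean_divide",
                                        "mean_divide_log10")) {
  kind <- match.arg(kind)
  if (!identical(scale_tag(x), "raw") && kind != "none") {
    abort(sprintf("table already carries scale '%s'; transforms apply to raw data",
                  scale_tag(x)), class = "slidenorm_scale_error")
  }
  if (kind == "none") return(x)
  chs <- channels(x)
  mu_tbl <- purrr::map(set_names(chs), function(ch) {
    s <- slide_summary(x, ch)
    if (kind != "log10") {
      bad <- s$slide_id[s$mu <= 0]
      if (length(bad)) {
        abort(sprintf("channel '%s': slide(s) %s have zero mean; mean division undefined",
                      ch, paste(bad, collapse = ", ")),
              class = "slidenorm_degenerate_slide_error")
      }
    }
    setNames(s$mu, s$slide_id)
  })
  out <- as_tibble(x)
  for (ch in chs) {
    out[[ch]] <- unname(switch(kind,
      log10 = transform_log10(out[[ch]]),
      mean_divide = transform_mean_divide(out[[ch]], mu_tbl[[ch]][out$slide_id]),
      mean_divide_log10 = transform_mean_divide_log10(out[[ch]], mu_tbl[[ch]][out$slide_id])
    ))
  }
  out <- new_cell_tbl(out, channels = chs, scale_tag = kind)
  attr(out, "transform_spec") <- structure(
    list(kind = kind, mu = mu_tbl), class = "transform_spec")
  out
}

#' Retrieve or serialize the transformation spec of a table
#'
#' @param x A `cell_tbl` produced by [apply_transform()].
#' @return The `transform_spec` (kind plus cached per-slide means), or `NULL`
#'   for untransformed tables.
#' @export
transform_spec <- function(x) attr(x, "transform_spec")

#' @param spec A `transform_spec`.
#' @param path JSON output path.
#' @rdname transform_spec
#' @export
write_transform_spec <- function(spec, path) {
  jsonlite::write_json(
    list(kind = spec$kind, mu = purrr::map(spec$mu, as.list)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname transform_spec
#' @export
read_transform_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    kind = raw$kind,
    mu = purrr::map(raw$mu, ~ unlist(.x))
  ), class = "transform_spec")
}
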