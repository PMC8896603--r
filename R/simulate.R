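#' Configuration for the synthetic cell-table generator
#'
#' Describes a multi-slide experiment with known slide-level batch effects.
#' Cells carry a latent tissue class (epithelium/stroma) that shifts the
#' four architecture channels, and immune channels carry a two-component
#' marker-positive/negative mixture. Per slide and channel, a mean effect
#' \eqn{\gamma_{ic} \sim N(0, \tau^2)} is added on the log scale and the
#' residual is scaled by \eqn{\delta_{ic}} with \eqn{\delta^2_{ic} \sim
#' IG(\omega, \beta)}; intensities are exponentiated and rounded to
#' non-negative integers, emulating right-skewed integer median-pixel
#' quantifications.
#'
#' @param n_slides Number of slides.
#' @param cells_per_slide Cells per slide: one number, or a length-2 range
#'   sampled uniformly per slide.
#' @param channels Channel names; defaults to four tissue-architecture
#'   markers (vimentin, collagen, panck, nakatpase) plus two immune markers
#'   (cd3, cd8).
#' @param tau SD of the additive log-scale slide mean effect.
#' @param delta_shape,delta_scale Inverse-gamma shape \eqn{\omega} (> 2) and
#'   scale \eqn{\beta} of the slide variance effect; the defaults give prior
#'   mean 1 with mild spread.
#' @param epithelium_prob Probability a cell is epithelial.
#' @param label_noise Probability that an emitted tissue/manual label is
#'   flipped relative to the truth (manual labels are a "bronze standard").
#' @param channel_params Optional tibble overriding the per-channel
#'   log-normal mixture parameters (see [default_channel_params()]).
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_slides = 20, cells_per_slide = 2000,
                       channels = c("vimentin", "collagen", "panck",
                                    "nakatpase", "cd3", "cd8"),
                       tau = 0.5, delta_shape = 50, delta_scale = 49,
                       epithelium_prob = 0.5, label_noise = 0.05,
                       channel_params = NULL, seed = 1L) {
  cfg <- list(n_slides = n_slides, cells_per_slide = cells_per_slide,
              channels = channels, tau = tau, delta_shape = delta_shape,
              delta_scale = delta_scale, epithelium_prob = epithelium_prob,
              label_noise = label_noise,
              channel_params = channel_params %||% default_channel_params(channels),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default per-channel mixture parameters
#'
#' Tissue channels draw from class-dependent log-normals (epithelium-high
#' for panck/nakatpase, stroma-high for vimentin/collagen); immune channels
#' draw a background/positive mixture. Log-means around 3 (background,
#' ~ e^3 = 20 counts) and 5 (expressing, ~ 150 counts) with log-SD 0.4-0.5
#' give the right-skewed, bimodal histograms typical of median-pixel
#' quantifications.
#'
#' @param channels Channel names; names containing `cd` are treated as
#'   immune markers.
#' @return A tibble with one row per channel.
#' @export
default_channel_params <- function(channels) {
  stroma_high <- c("vimentin", "collagen")
  purrr::map(channels, function(ch) {
    if (grepl("cd", ch)) {
      tibble(channel = ch, type = "immune",
             lo_logmean = 3, lo_logsd = 0.5,
             hi_logmean = 5, hi_logsd = 0.4, pos_frac = 0.3)
    } else {
      tibble(channel = ch, type = "tissue",
             lo_logmean = 3, lo_logsd = 0.5,
             hi_logmean = 5, hi_logsd = 0.5,
             pos_frac = NA_real_,
             high_class = if (ch %in% stroma_high) "stroma" else "epithelium")
    }
  }) |> bind_rows()
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("invalid sim_config field '%s': %s", field, msg),
          class = "slidenorm_config_error")
  }
  if (length(cfg$n_slides) != 1 || cfg$n_slides < 1) bad("n_slides", "must be >= 1")
  if (!length(cfg$cells_per_slide) %in% c(1, 2) || any(cfg$cells_per_slide < 1)) {
    bad("cells_per_slide", "must be a positive count or range")
  }
  if (cfg$tau < 0) bad("tau", "must be >= 0")
  if (cfg$delta_shape <= 2) bad("delta_shape", "must be > 2 for finite prior variance")
  if (cfg$delta_scale <= 0) bad("delta_scale", "must be > 0")
  if (cfg$epithelium_prob <= 0 || cfg$epithelium_prob >= 1) {
    bad("epithelium_prob", "must be in (0, 1)")
  }
  if (cfg$label_noise < 0 || cfg$label_noise >= 0.5) {
    bad("label_noise", "must be in [0, 0.5)")
  }
  cp <- cfg$channel_params
  if (any(c(cp$lo_logsd, cp$hi_logsd) <= 0)) bad("channel_params", "log-SDs must be > 0")
  pf <- cp$pos_frac[!is.na(cp$pos_frac)]
  if (any(pf <= 0 | pf >= 1)) bad("channel_params", "pos_frac must be in (0, 1)")
  invisible(cfg)
}

#' Simulate a cell-quantification table with known slide effects
#'
#' Draws a multi-slide cell table from the generative model described in
#' [sim_config()] and returns it together with the ground truth (the true
#' per-slide-channel mean and variance effects, and every cell's true tissue
#' class and marker-positivity), so that effect recovery and metric
#' calibration can be tested without external data. Fully deterministic
#' given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A list with `table` (a raw-scale `cell_tbl` with noisy emitted
#'   labels), `truth` (list: `slide_effects` tibble and `cells` tibble), and
#'   `config`.
#' @export
#' @examples
#' sim <- simulate_table(sim_config(n_slides = 3, cells_per_slide = 100, seed = 7))
#' sim$truth$slide_effects
simulate_table <- function(config) {
  validate_sim_config(config)
  cp <- config$channel_params
  withr::with_seed(config$seed, {
    slide_ids <- sprintf("s%02d", seq_len(config$n_slides))
    n_cells <- if (length(config$cells_per_slide) == 2) {
      sample(config$cells_per_slide[1]:config$cells_per_slide[2],
             config$n_slides, replace = TRUE)
    } else rep(config$cells_per_slide, config$n_slides)
    total <- sum(n_cells)
    slide <- rep(slide_ids, n_cells)

    effects <- tidyr::expand_grid(slide_id = slide_ids, channel = cp$channel) |>
      mutate(gamma = rnorm(dplyr::n(), 0, config$tau),
             delta2 = 1 / rgamma(dplyr::n(), shape = config$delta_shape,
                                 rate = config$delta_scale))

    tissue_true <- ifelse(rbinom(total, 1, config$epithelium_prob) == 1,
                          "epithelium", "stroma")
    tbl <- tibble(slide_id = slide,
                  cell_id = sprintf("cell_%06d", seq_len(total)))
    truth_cells <- tibble(cell_id = tbl$cell_id, tissue_class = tissue_true)

    for (j in seq_len(nrow(cp))) {
      ch <- cp$channel[j]
      eff <- effects |> filter(.data$channel == ch)
      g <- setNames(eff$gamma, eff$slide_id)[slide]
      d <- sqrt(setNames(eff$delta2, eff$slide_id)[slide])
      if (cp$type[j] == "immune") {
        pos <- rbinom(total, 1, cp$pos_frac[j]) == 1
        mu <- ifelse(pos, cp$hi_logmean[j], cp$lo_logmean[j])
        sdv <- ifelse(pos, cp$hi_logsd[j], cp$lo_logsd[j])
        truth_cells[[paste0("positive_", ch)]] <- pos
      } else {
        hi <- tissue_true == cp$high_class[j]
        mu <- ifelse(hi, cp$hi_logmean[j], cp$lo_logmean[j])
        sdv <- ifelse(hi, cp$hi_logsd[j], cp$lo_logsd[j])
      }
      log_y <- mu + g + d * sdv * rnorm(total)
      tbl[[ch]] <- pmax(round(exp(log_y)), 0)
    }

    flip <- function(v) {
      f <- rbinom(total, 1, config$label_noise) == 1
      ifelse(f, !v, v)
    }
    tbl$tissue_class <- ifelse(flip(tissue_true == "epithelium"),
                               "epithelium", "stroma")
    for (ch in cp$channel[cp$type == "immune"]) {
      tbl[[paste0("manual_pos_", ch)]] <-
        as.integer(flip(truth_cells[[paste0("positive_", ch)]]))
    }
    tbl$tumor_region <- rbinom(total, 1, 0.3)
  })
  table <- cell_table(tbl, slide_col = "slide_id", channels = cp$channel,
                      cell_col = "cell_id", scale_tag = "raw")
  list(table = table,
       truth = list(slide_effects = effects, cells = truth_cells),
       config = config)
}

#' A small fixed fixture table for exact-value tests
#'
#' Regenerates a deterministic 3-slide, 60-cells-per-slide, 2-channel table
#' (180 cells) with noise-free labels. A frozen copy ships in
#' `inst/extdata/fixture_small.csv` with a sidecar documenting its slide
#' means; tests verify the regeneration matches the shipped copy.
#'
#' @return A list with `table`, `truth`, `config` (as [simulate_table()]).
#' @export
fixture_small <- function() {
  simulate_table(sim_config(
    n_slides = 3, cells_per_slide = 60,
    channels = c("vimentin", "cd3"),
    tau = 0.5, label_noise = 0, seed = 424242L))
}

#' Write a simulation's truth to JSON
#'
#' @param sim Output of [simulate_table()].
#' @param path JSON output path.
#' @export
write_sim_truth <- function(sim, path) {
  jsonlite::write_json(
    list(slide_effects = sim$truth$slide_effects, cells = sim$truth$cells,
         seed = sim$config$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
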