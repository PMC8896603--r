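#' Cell-quantification tables
#'
#' A cell table holds one row per segmented cell: an opaque slide identifier, a
#' unique cell identifier, one non-negative intensity column per marker channel
#' (raw values are integer-valued median pixel intensities), and optional
#' biological label columns (`tissue_class`, `tumor_region`, and per-channel
#' `manual_pos_<channel>` flags). A `scale_tag` attribute records which
#' transformation, if any, has been applied, so downstream steps can refuse
#' double application.
#'
#' @param x A data frame with at least a slide column and one intensity column.
#' @param slide_col Name of the column holding the slide identifier.
#' @param channels Character vector of intensity column names. If `NULL`, all
#'   numeric columns other than recognised label columns are used.
#' @param cell_col Name of the unique cell-identifier column, or `NULL` to
#'   generate sequential identifiers.
#' @param scale_tag Provenance tag; `"raw"` for untransformed integer data.
#' @param validate Run [validate_cell_table()] on the result.
#'
#' @return A tibble of class `cell_tbl` with columns `slide_id`, `cell_id`,
#'   one column per channel, and any label columns, plus attributes
#'   `channels` and `scale_tag`.
#' @export
#' @examples
#' tbl <- cell_table(
#'   data.frame(slide = c("s1", "s1", "s2"), cd3 = c(2, 4, 6)),
#'   slide_col = "slide"
#' )
#' slide_summary(tbl, "cd3")
cell_table <- function(x, slide_col = "slide_id", channels = NULL,
                       cell_col = NULL, scale_tag = "raw", validate = TRUE) {
  x <- as_tibble(x)
  if (!slide_col %in% names(x)) {
    abort(sprintf("slide column '%s' not found", slide_col), class = "slidenorm_schema_error")
  }
  label_cols <- intersect(names(x), c("tissue_class", "tumor_region",
                                      grep("^manual_pos_", names(x), value = TRUE)))
  if (is.null(channels)) {
    cand <- setdiff(names(x), c(slide_col, cell_col, "cell_id", label_cols))
    channels <- cand[vapply(x[cand], is.numeric, logical(1))]
  }
  if (length(channels) == 0) {
    abort("no intensity channels found or named", class = "slidenorm_schema_error")
  }
  missing_ch <- setdiff(channels, names(x))
  if (length(missing_ch)) {
    abort(sprintf("channel column(s) not found: %s", paste(missing_ch, collapse = ", ")),
          class = "slidenorm_schema_error")
  }
  out <- tibble(
    slide_id = as.character(x[[slide_col]]),
    cell_id = if (is.null(cell_col)) sprintf("cell_%06d", seq_len(nrow(x)))
              else as.character(x[[cell_col]])
  )
  for (ch in channels) out[[ch]] <- as.numeric(x[[ch]])
  for (lc in label_cols) out[[lc]] <- x[[lc]]
  out <- new_cell_tbl(out, channels = channels, scale_tag = scale_tag)
  if (validate) validate_cell_table(out)
  out
}

new_cell_tbl <- function(df, channels, scale_tag) {
  structure(df,
            channels = channels,
            scale_tag = scale_tag,
            class = c("cell_tbl", class(tibble())))
}

#' @export
print.cell_tbl <- function(x, ...) {
  cat(sprintf("# A cell table: %d cells x %d channels, %d slide(s), scale '%s'\n",
              nrow(x), length(channels(x)), dplyr::n_distinct(x$slide_id),
              scale_tag(x)))
  NextMethod()
}

#' Channel names and scale tag of a cell table
#'
#' @param x A `cell_tbl`.
#' @return `channels()` a character vector of marker channel names;
#'   `scale_tag()` the provenance tag of the intensity scale.
#' @export
channels <- function(x) attr(x, "channels")

#' @rdname channels
#' @export
scale_tag <- function(x) attr(x, "scale_tag")

#' Validate a cell table
#'
#' Checks the structural invariants: non-empty, at least one slide, unique cell
#' identifiers, no missing intensities, and (on the raw scale) non-negative
#' intensities. All-zero slide-channel combinations are flagged with a warning
#' because mean division is undefined for them.
#'
#' @param x A `cell_tbl`.
#' @return `x`, invisibly. Errors have class `slidenorm_validation_error`.
#' @export
validate_cell_table <- function(x) {
  chs <- channels(x)
  if (nrow(x) == 0) abort("cell table has no rows", class = "slidenorm_validation_error")
  if (anyDuplicated(x$cell_id)) {
    abort("cell_id values are not unique", class = "slidenorm_validation_error")
  }
  for (ch in chs) {
    v <- x[[ch]]
    if (!is.numeric(v)) {
      abort(sprintf("channel '%s' is not numeric", ch), class = "slidenorm_parse_error")
    }
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf("missing intensity in channel '%s' at cell '%s'", ch, x$cell_id[i]),
            class = "slidenorm_validation_error")
    }
    if (identical(scale_tag(x), "raw") && any(v < 0)) {
      i <- which(v < 0)[1]
      abort(sprintf("negative raw intensity %g in channel '%s' at cell '%s' (slide '%s')",
                    v[i], ch, x$cell_id[i], x$slide_id[i]),
            class = "slidenorm_validation_error")
    }
    mu <- tapply(v, x$slide_id, mean)
    if (any(mu == 0)) {
      warn(sprintf("channel '%s': slide(s) %s have all-zero intensities (mean division undefined)",
                   ch, paste(names(mu)[mu == 0], collapse = ", ")),
           class = "slidenorm_degenerate_slide_warning")
    }
  }
  invisible(x)
}

#' Read a cell-quantification table from CSV
#'
#' Reads a comma-separated table with a header row and validates it. If a
#' companion metadata file `<path>.meta.json` (as written by
#' [write_cell_table()]) exists, the recorded schema and scale tag are applied;
#' explicit arguments override it.
#'
#' @param path Path to the CSV file.
#' @param slide_col,channels,cell_col,scale_tag See [cell_table()]. Defaults
#'   come from the sidecar metadata when present.
#' @return A validated `cell_tbl`.
#' @export
read_cell_table <- function(path, slide_col = NULL, channels = NULL,
                            cell_col = NULL, scale_tag = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  slide_col <- slide_col %||% meta$slide_col %||% "slide_id"
  channels <- channels %||% meta$channels
  cell_col <- cell_col %||% meta$cell_col
  scale_tag <- scale_tag %||% meta$scale_tag %||% "raw"
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cell_table(df, slide_col = slide_col, channels = channels,
             cell_col = cell_col, scale_tag = scale_tag)
}

#' Write a cell-quantification table to CSV
#'
#' Writes the table as plain CSV plus a companion `<path>.meta.json` recording
#' the schema (slide/cell columns, channel names) and the scale tag, so
#' [read_cell_table()] restores the same column roles and provenance.
#'
#' @param x A `cell_tbl`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path) {
  validate_cell_table(x)
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  meta <- list(slide_col = "slide_id", cell_col = "cell_id",
               channels = channels(x), scale_tag = scale_tag(x))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Per-slide mean intensity and cell count
#'
#' For one marker channel, returns the slide mean \eqn{\mu_{ic}} of the cell
#' intensities and the number of quantified cells \eqn{U_{ic}} on each slide.
#' These are the quantities the mean-division transforms and the ComBat model
#' are built on.
#'
#' @param x A `cell_tbl`.
#' @param channel Marker channel name.
#' @return A tibble with columns `slide_id`, `mu`, `n_cells`.
#' @export
slide_summary <- function(x, channel) {
  if (!channel %in% channels(x)) {
    abort(sprintf("unknown channel '%s'", channel), class = "slidenorm_schema_error")
  }
  as_tibble(x) |>
    group_by(.data$slide_id) |>
    summarise(mu = mean(.data[[channel]]), n_cells = dplyr::n(), .groups = "drop") |>
    arrange(.data$slide_id)
}
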