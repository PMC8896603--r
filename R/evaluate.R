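#' UMAP embedding and clustering-based label separation
#'
#' Embeds a slide-stratified subsample of cells into two dimensions with UMAP
#' using a small panel of markers (the tissue-architecture panel by default),
#' clusters the embedding with k-means (k = number of distinct labels), and
#' scores the agreement between clusters and labels with the adjusted Rand
#' index. With tissue labels, high ARI means biological signal is preserved;
#' with slide identifiers, low ARI means slide effects are gone.
#'
#' @param x A `cell_tbl`.
#' @param use_channels Marker channels for the embedding (typically 4).
#' @param labels Label per cell (vector), or the name of a label column in
#'   `x`, or `"slide_id"`.
#' @param frac Subsample fraction, stratified by slide (default 0.10).
#' @param seed Seed controlling subsampling, UMAP and k-means.
#' @param n_neighbors,min_dist UMAP tuning parameters.
#' @return A list with `embedding` (tibble: `umap1`, `umap2`, `slide_id`,
#'   `label`, `cluster`) and `ari`.
#' @export
embedding_ari <- function(x, use_channels, labels, frac = 0.10, seed = 1,
                          n_neighbors = 15, min_dist = 0.1) {
  missing_ch <- setdiff(use_channels, channels(x))
  if (length(missing_ch)) {
    abort(sprintf("channel(s) not in table: %s", paste(missing_ch, collapse = ", ")))
  }
  if (is.character(labels) && length(labels) == 1) {
    if (!labels %in% names(x)) abort(sprintf("label column '%s' not found", labels))
    labels <- x[[labels]]
  }
  if (length(labels) != nrow(x)) abort("labels length must match cell count")
  if (dplyr::n_distinct(labels) < 2) abort("need at least 2 distinct labels")
  withr::with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(x)), x$slide_id), function(i) {
      sample(i, max(1L, round(length(i) * frac)))
    }), use.names = FALSE)
    mat <- as.matrix(as_tibble(x)[idx, use_channels])
    lab <- labels[idx]
    emb <- uwot::umap(mat, n_neighbors = min(n_neighbors, nrow(mat) - 1),
                      min_dist = min_dist, metric = "euclidean",
                      n_threads = 1, n_sgd_threads = 0)
    k <- dplyr::n_distinct(lab)
    km <- stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100)
  })
  list(
    embedding = tibble(umap1 = emb[, 1], umap2 = emb[, 2],
                       slide_id = x$slide_id[idx],
                       label = as.character(lab), cluster = km$cluster),
    ari = adjusted_rand_index(km$cluster, lab)
  )
}

#' Evaluate a normalization method
#'
#' Runs the full evaluation battery on a normalized table: per channel, the
#' k-sample Anderson-Darling alignment statistic across slides, the mean
#' Otsu threshold discordance score, and the slide-level variance proportion
#' from a random-intercept model; their cross-channel means; embedding-based
#' adjusted Rand indices for slide identifiers (lower = better slide-effect
#' removal) and, when tissue labels are present, for tissue class (higher =
#' better signal preservation); and marker-positive accuracy against any
#' manual labels carried by the table. All metrics except accuracy and
#' tissue ARI are oriented so that smaller is better.
#'
#' @param table_raw The raw-scale `cell_tbl` (carries the manual labels and
#'   provides the reference cells/slides).
#' @param table_norm The transformed/normalized `cell_tbl` to score.
#' @param method Method name for the report (default: the normalized table's
#'   scale tag).
#' @param use_channels Channels to score; default all.
#' @param embed_channels Channels for the UMAP embeddings; default the first
#'   four scored channels. Set `embedding = FALSE` to skip embeddings.
#' @param embedding Compute the embedding ARIs (the slowest component).
#' @param frac,seed Subsample fraction and seed for [embedding_ari()].
#' @param nbins Histogram bins for Otsu thresholds.
#' @return An `eval_report`; see [tidy.eval_report()] and
#'   [glance.eval_report()].
#' @export
evaluate_method <- function(table_raw, table_norm, method = NULL,
                            use_channels = NULL, embed_channels = NULL,
                            embedding = TRUE, frac = 0.10, seed = 1,
                            nbins = 256) {
  if (nrow(table_raw) != nrow(table_norm) ||
      !identical(table_raw$cell_id, table_norm$cell_id)) {
    abort("raw and normalized tables must contain the same cells in the same order")
  }
  chs <- use_channels %||% channels(table_norm)
  method <- method %||% scale_tag(table_norm)
  per_channel <- purrr::map(set_names(chs), function(ch) {
    y <- table_norm[[ch]]
    tibble(
      channel = ch,
      ad_stat = ad_ksample(split(y, table_norm$slide_id)),
      otsu_discordance = otsu_discordance(table_norm, ch, nbins = nbins)$mean,
      variance_prop = variance_proportion(y, table_norm$slide_id)
    )
  }) |> bind_rows()

  accuracy <- NULL
  man_cols <- grep("^manual_pos_", names(table_raw), value = TRUE)
  man_chs <- intersect(sub("^manual_pos_", "", man_cols), chs)
  if (length(man_chs)) {
    accuracy <- tibble(
      channel = man_chs,
      accuracy = vapply(man_chs, function(ch) {
        marker_positive_accuracy(table_norm, ch,
                                 labels = table_raw[[paste0("manual_pos_", ch)]],
                                 nbins = nbins)
      }, numeric(1)))
  }

  ari_slide <- NA_real_
  ari_tissue <- NA_real_
  if (embedding) {
    emb_chs <- embed_channels %||% head(chs, 4)
    ari_slide <- embedding_ari(table_norm, emb_chs, labels = "slide_id",
                               frac = frac, seed = seed)$ari
    if ("tissue_class" %in% names(table_raw)) {
      ari_tissue <- embedding_ari(table_norm, emb_chs,
                                  labels = table_raw$tissue_class,
                                  frac = frac, seed = seed)$ari
    } else {
      warn("no tissue_class labels; tissue ARI not computed")
    }
  }

  structure(list(method = method, per_channel = per_channel,
                 accuracy = accuracy, ari_slide = ari_slide,
                 ari_tissue = ari_tissue, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("# Evaluation report for method '%s'\n", x$method))
  print(glance(x))
  invisible(x)
}

#' Tidy and summarize an evaluation report
#'
#' `tidy()` returns the per-channel metric table; `glance()` the one-row
#' cross-channel summary (method, mean AD statistic, mean Otsu discordance
#' score, slide-ID adjusted Rand index, mean slide variance proportion, plus
#' tissue ARI and mean marker-positive accuracy when available).
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$per_channel

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    method = x$method,
    mean_ad_stat = mean(x$per_channel$ad_stat),
    mean_otsu_discordance = mean(x$per_channel$otsu_discordance),
    ari_slide = x$ari_slide,
    mean_variance_prop = mean(x$per_channel$variance_prop),
    ari_tissue = x$ari_tissue,
    mean_accuracy = if (is.null(x$accuracy)) NA_real_ else mean(x$accuracy$accuracy)
  )
}

#' Serialize evaluation reports
#'
#' `write_eval_report()` writes the one-row summaries of one or more reports
#' as a CSV (one row per method, mirroring a methods-comparison table) and,
#' alongside it, a JSON file with the per-channel detail.
#' `read_eval_report()` reads the summary CSV back as a tibble.
#'
#' @param reports An `eval_report` or a list of them.
#' @param path Output CSV path; the JSON detail goes to `<path>.detail.json`.
#' @export
write_eval_report <- function(reports, path) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  summary <- bind_rows(purrr::map(reports, glance))
  readr::write_csv(summary, path, progress = FALSE)
  detail <- purrr::map(reports, function(r) {
    list(method = r$method,
         per_channel = r$per_channel,
         accuracy = r$accuracy)
  })
  jsonlite::write_json(detail, paste0(path, ".detail.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
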