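#' Feature tables
#'
#' A feature table is a tibble with one row per sample: identifier and
#' metadata columns (`sample_id`, and any of `class`, `survival_months`,
#' `qc_injected`) followed by numeric feature columns holding normalized
#' relative concentrations.  Per-feature metadata (retention index, putative
#' identity) and scaling state travel as attributes and are re-derived where
#' dplyr verbs drop them.
#'
#' @param x A data frame.
#' @name feature_table
NULL

META_COLS <- c("sample_id", "class", "survival_months", "qc_injected")

#' Names of the feature columns of a feature table
#' @param x A feature table (data frame).
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(x) {
  setdiff(names(x), META_COLS)
}

#' Extract the sample-by-feature matrix of a feature table
#' @param x A feature table (data frame).
#' @return Numeric matrix, rownames = sample ids.
#' @export
feature_matrix <- function(x) {
  fc <- feature_cols(x)
  m <- as.matrix(as.data.frame(x)[, fc, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x$sample_id)
  m
}

#' Assemble a feature table from a matrix and sample metadata
#'
#' @param X Numeric matrix, samples in rows, features in columns.
#' @param sample_meta Data frame with a `sample_id` column (and optionally
#'   `class`, `survival_months`).  Row order must match `X`.
#' @param feature_meta Optional data frame with columns `feature` and any of
#'   `ri`, `putative_id`; attached as the `feature_meta` attribute.
#' @return A feature-table tibble.
#' @export
as_feature_table <- function(X, sample_meta, feature_meta = NULL) {
  stopifnot(nrow(X) == nrow(sample_meta), "sample_id" %in% names(sample_meta))
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("F%03d", seq_len(ncol(X)))
  }
  tbl <- dplyr::bind_cols(
    tibble::as_tibble(sample_meta),
    tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  )
  if (!is.null(feature_meta)) attr(tbl, "feature_meta") <- tibble::as_tibble(feature_meta)
  tbl
}

#' Retrieve per-feature metadata attached to a feature table
#' @param x A feature table.
#' @return A tibble with one row per feature (at minimum the feature id).
#' @export
feature_meta <- function(x) {
  fm <- attr(x, "feature_meta")
  if (is.null(fm)) fm <- tibble::tibble(feature = feature_cols(x))
  fm
}

#' Retrieve simulation ground truth attached to a generated table or cube
#' @param x An object produced by [simulate_feature_table()] or
#'   [simulate_cube()].
#' @return The ground-truth list, or `NULL` when absent.
#' @export
ground_truth <- function(x) attr(x, "truth", exact = TRUE)
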