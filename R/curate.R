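#' Curate a feature table before modeling
#'
#' Applies the standard pre-modeling clean-up, logging every action with a
#' reason:
#' \itemize{
#'   \item artifact features — (near-)constant columns — are dropped;
#'   \item failed samples — a majority of features collapsed to near zero
#'     (the derivatization-failure signature) — are dropped;
#'   \item gross analytical outliers — samples beyond five interquartile
#'     ranges from the score medians on the first two principal components
#'     of the log-transformed table — are dropped (a robust rule that does
#'     not discard ordinary samples the way a 95% ellipse's ~5% chance rate
#'     would; the log scale keeps skewed but ordinary profiles inside the
#'     fence).
#' }
#' If more than a quarter of the samples would be dropped the function
#' aborts, which guards against mis-scaled input.
#'
#' @param table A feature table.
#' @param artifact_rel_sd Features with SD/|mean| below this are artifacts.
#' @param failed_frac A sample is "failed" when at least this fraction of
#'   its features lies below 1% of the feature median.
#' @return List with `table` (curated) and `log` (tibble: id, type,
#'   reason).
#' @export
curate_table <- function(table, artifact_rel_sd = 1e-6, failed_frac = 0.5) {
  log <- tibble::tibble(id = character(), type = character(),
                        reason = character())
  X <- feature_matrix(table)

  # artifact features: no usable variance
  rel_sd <- apply(X, 2L, sd) / pmax(abs(colMeans(X)), .Machine$double.eps)
  bad_feat <- colnames(X)[rel_sd < artifact_rel_sd]
  if (length(bad_feat) > 0L) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      id = bad_feat, type = "feature", reason = "artifact (near-zero variance)"))
    table <- table[, setdiff(names(table), bad_feat)]
    X <- X[, setdiff(colnames(X), bad_feat), drop = FALSE]
  }

  # failed samples: majority of features near zero
  med <- apply(X, 2L, median)
  frac_low <- rowMeans(sweep(X, 2L, 0.01 * med, `<`))
  failed <- which(frac_low >= failed_frac)

  # gross outliers among the remaining samples: robust score-space rule on
  # log-transformed values (relative concentrations are log-normal, so the
  # log scale keeps ordinary samples inside the interquartile fence)
  keep1 <- setdiff(seq_len(nrow(X)), failed)
  outl <- integer(0)
  if (length(keep1) >= 4L && ncol(X) >= 2L) {
    L <- log(pmax(X[keep1, , drop = FALSE], .Machine$double.xmin))
    sc <- prcomp(L, center = TRUE, rank. = min(2L, length(keep1) - 1L))$x
    robust <- rep(FALSE, nrow(sc))
    for (j in seq_len(ncol(sc))) {
      iqr <- stats::IQR(sc[, j])
      if (iqr > 0) robust <- robust | abs(sc[, j] - median(sc[, j])) > 5 * iqr
    }
    outl <- keep1[robust]
  }

  drop <- sort(unique(c(failed, outl)))
  if (length(drop) > 0.25 * nrow(X)) {
    abort(sprintf("curation would drop %d of %d samples; input looks mis-scaled",
                  length(drop), nrow(X)))
  }
  ids <- as.character(table$sample_id)
  if (length(failed) > 0L) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      id = ids[failed], type = "sample",
      reason = "failed (majority of features near zero)"))
  }
  if (length(outl) > 0L) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      id = ids[outl], type = "sample",
      reason = "outlier (scores > 5 IQR from median)"))
  }
  out <- if (length(drop) > 0L) table[-drop, ] else table
  attr(out, "feature_meta") <- {
    fm <- feature_meta(table); fm[fm$feature %in% feature_cols(out), ]
  }
  list(table = out, log = log)
}

#' Survival grouping presets
#'
#' Named short/long survival break-points (months): `gbm` compares patients
#' who died within 4 months of diagnosis to those who lived 3 years or
#' more; `oligodendroglioma` compares death within 2 years to survival of
#' 3 years or more.
#'
#' @format A named list of `c(short_max, long_min)` pairs.
#' @export
survival_presets <- list(
  gbm = c(short_max = 4, long_min = 36),
  oligodendroglioma = c(short_max = 24, long_min = 36)
)

#' Dichotomize survival times into short/long classes
#'
#' Survival at or below `short_max` months is the short class (coded 0);
#' at or above `long_min` months the long class (coded 1); strictly between
#' the two break-points the sample is excluded from the comparison.
#'
#' @param meta Data frame with `sample_id` and `survival_months`.
#' @param short_max Upper bound (months) of the short-survival class.
#' @param long_min Lower bound (months) of the long-survival class;
#'   must exceed `short_max`.  Or pass a preset name from
#'   [survival_presets] as `preset`.
#' @param preset Optional name: `"gbm"` or `"oligodendroglioma"`.
#' @return Tibble `sample_id`, `survival_months`, `class` (0 short, 1 long,
#'   `NA` excluded).
#' @export
assign_survival_classes <- function(meta, short_max = NULL, long_min = NULL,
                                    preset = NULL) {
  if (!is.null(preset)) {
    if (!preset %in% names(survival_presets)) {
      abort(sprintf("unknown preset '%s'", preset))
    }
    short_max <- survival_presets[[preset]][["short_max"]]
    long_min <- survival_presets[[preset]][["long_min"]]
  }
  if (is.null(short_max) || is.null(long_min) || short_max >= long_min) {
    abort("`short_max` must be below `long_min`")
  }
  s <- meta$survival_months
  cls <- dplyr::case_when(s <= short_max ~ 0L, s >= long_min ~ 1L,
                          TRUE ~ NA_integer_)
  if (sum(cls == 0L, na.rm = TRUE) == 0L || sum(cls == 1L, na.rm = TRUE) == 0L) {
    abort("survival grouping left a class empty")
  }
  tibble::tibble(sample_id = as.character(meta$sample_id),
                 survival_months = s, class = cls)
}
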