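#' Column-wise scaling of a feature table
#'
#' Centers every feature column and optionally divides by the column SD
#' (`uv`, unit variance — the default convention for metabolomics OPLS-DA)
#' or its square root (`pareto`).  The centering/scaling vectors are stored
#' in the `scaling` attribute so the identical transform can be applied to
#' held-out data with [apply_scaling()].
#'
#' @param table An unscaled feature table.
#' @param mode One of `"uv"`, `"pareto"`, `"center"`.
#' @return The scaled table; attribute `scaling` holds `mode`, `center`,
#'   `scale` and the feature names; zero-variance columns are dropped with a
#'   warning under `uv`/`pareto`.
#' @export
scale_features <- function(table, mode = c("uv", "pareto", "center")) {
  mode <- match.arg(mode)
  if (!is.null(attr(table, "scaling"))) abort("table is already scaled")
  X <- feature_matrix(table)
  ctr <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  if (mode != "center" && any(sdv == 0)) {
    warn(sprintf("dropping %d zero-variance feature(s)", sum(sdv == 0)))
    keep <- sdv > 0
    X <- X[, keep, drop = FALSE]
    ctr <- ctr[keep]; sdv <- sdv[keep]
  }
  scl <- switch(mode, uv = sdv, pareto = sqrt(sdv), center = rep(1, length(sdv)))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  meta <- as.data.frame(table)[, intersect(META_COLS, names(table)), drop = FALSE]
  out <- as_feature_table(Xs, meta, feature_meta = attr(table, "feature_meta"))
  attr(out, "truth") <- attr(table, "truth", exact = TRUE)
  attr(out, "scaling") <- list(mode = mode, center = ctr, scale = scl,
                               features = colnames(X))
  out
}

#' Apply a stored scaling to new data
#' @param table An unscaled feature table with the same feature columns.
#' @param scaling The `scaling` attribute of a table scaled by
#'   [scale_features()].
#' @return The scaled table (same attribute attached).
#' @export
apply_scaling <- function(table, scaling) {
  X <- feature_matrix(table)[, scaling$features, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, scaling$center), 2L, scaling$scale, `/`)
  meta <- as.data.frame(table)[, intersect(META_COLS, names(table)), drop = FALSE]
  out <- as_feature_table(Xs, meta, feature_meta = attr(table, "feature_meta"))
  attr(out, "scaling") <- scaling
  out
}
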