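#' PCA overview with Hotelling-T2 outlier screening
#'
#' Unsupervised overview of a feature table: successive orthogonal
#' components maximizing explained variance (via [stats::prcomp()]), with
#' two outlier screens on the first two components — the classical
#' Hotelling-T2 95% ellipse, and a robust flag for samples more than five
#' interquartile ranges from the score medians (the signature of a gross
#' analytical outlier; immune to the ~5% chance rate of the 95% ellipse).
#'
#' @param table A feature table (any scaling state; columns are centered
#'   internally, not rescaled).
#' @param n_components Number of components (<= min(samples-1, features)).
#' @return A `pca_overview` object: `scores` tibble (sample_id, PC columns,
#'   `t2`, `outlier`, `robust_outlier`), `loadings`, `r2x` (per-component
#'   fraction of variance), `t2_limit`.
#' @export
pca_overview <- function(table, n_components = 2L) {
  nc <- check_count(n_components, "n_components")
  X <- feature_matrix(table)
  n <- nrow(X)
  if (nc > min(n - 1L, ncol(X))) abort("`n_components` too large for this table")
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = nc)
  scores <- pc$x
  tot_var <- sum(apply(X, 2L, var)) * (n - 1L)
  r2x <- (pc$sdev^2 * (n - 1L) / tot_var)[seq_len(nc)]

  k2 <- min(2L, nc)
  s2 <- apply(scores[, seq_len(k2), drop = FALSE], 2L, var)
  t2 <- rowSums(sweep(scores[, seq_len(k2), drop = FALSE]^2, 2L, s2, `/`))
  t2_limit <- k2 * (n - 1) / (n - k2) * qf(0.95, k2, n - k2)
  robust <- rep(FALSE, n)
  for (j in seq_len(k2)) {
    med <- median(scores[, j]); iqr <- stats::IQR(scores[, j])
    if (iqr > 0) robust <- robust | abs(scores[, j] - med) > 5 * iqr
  }

  structure(list(
    scores = dplyr::bind_cols(
      tibble::tibble(sample_id = as.character(table$sample_id)),
      tibble::as_tibble(scores),
      tibble::tibble(t2 = t2, outlier = t2 > t2_limit, robust_outlier = robust)
    ),
    loadings = pc$rotation,
    r2x = r2x,
    t2_limit = t2_limit,
    center = pc$center
  ), class = "pca_overview")
}

#' @export
print.pca_overview <- function(x, ...) {
  cat(sprintf("<pca_overview> %d components, R2X = %s\n",
              length(x$r2x), paste(sprintf("%.3f", x$r2x), collapse = ", ")))
  n_out <- sum(x$scores$outlier)
  cat(sprintf("  Hotelling-T2 95%% limit %.2f: %d sample(s) flagged (%d robust)\n",
              x$t2_limit, n_out, sum(x$scores$robust_outlier)))
  invisible(x)
}

#' @export
tidy.pca_overview <- function(x, ...) x$scores

#' @export
glance.pca_overview <- function(x, ...) {
  tibble::tibble(n_components = length(x$r2x), r2x_cum = sum(x$r2x),
                 t2_limit = x$t2_limit, n_outliers = sum(x$scores$outlier))
}

#' @rdname autoplot.opls_cv
#' @export
autoplot.pca_overview <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
    ggplot2::labs(
      x = sprintf("t[1] (%.1f%%)", 100 * object$r2x[1]),
      y = sprintf("t[2] (%.1f%%)", 100 * object$r2x[2]),
      colour = "T2 > 95% limit"
    ) +
    ggplot2::theme_minimal()
}
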