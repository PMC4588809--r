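#' Seven-fold cross-validation of an OPLS-DA model
#'
#' Deterministic stratified k-fold cross-validation: samples are sorted by
#' class then original order and dealt round-robin into `k` folds, so every
#' sample is predicted exactly once.  Scaling is refit inside each training
#' split and applied to the held-out samples; the held-out predictive
#' scores (`tcv`, the cross-validated score pattern) and response
#' predictions are collected.  `Q2 = 1 - PRESS/SS`, with PRESS the sum of
#' squared held-out response errors and SS the total centered response sum
#' of squares.  When a class has fewer members than `k`, the round-robin
#' deal degrades gracefully to leaving single class members out.
#'
#' @param table An unscaled feature table.
#' @param y Binary response (0/1, logical, or two-level factor).
#' @param A_orth Orthogonal component count for every fold model.
#' @param k Fold count (default 7).
#' @param scaling Scaling mode refit per split (see [scale_features()]).
#' @return An `opls_cv` object: `samples` tibble (`sample_id`, `y`, `fold`,
#'   `tcv`, `y_hat`), `Q2`, `PRESS`, `SS`, `k`, `A_orth`, `scaling`.
#' @export
cross_validate <- function(table, y, A_orth = 0L, k = 7L,
                           scaling = c("uv", "pareto", "center")) {
  scaling <- match.arg(scaling)
  k <- check_count(k, "k", min = 2L)
  y <- as_binary(y)
  n <- nrow(table)
  if (k > n) abort("`k` must not exceed the number of samples")
  X <- feature_matrix(table)
  sid <- as.character(table$sample_id)

  fold <- integer(n)
  fold[order(y, seq_len(n))] <- rep_len(seq_len(k), n)

  tcv <- y_hat <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[train])) < 2L) {
      abort("a training split lost one class entirely; reduce `k`")
    }
    Xtr <- X[train, , drop = FALSE]
    ctr <- colMeans(Xtr)
    sdv <- apply(Xtr, 2L, sd)
    scl <- switch(scaling, uv = sdv, pareto = sqrt(sdv),
                  center = rep(1, length(sdv)))
    scl[scl == 0] <- 1
    Xtr_s <- sweep(sweep(Xtr, 2L, ctr), 2L, scl, `/`)
    fitc <- opls_core(Xtr_s, y[train], A_orth)
    Xte_s <- sweep(sweep(X[test, , drop = FALSE], 2L, ctr), 2L, scl, `/`)
    for (i in seq_len(A_orth)) {
      t_o <- Xte_s %*% fitc$w_orth[, i]
      Xte_s <- Xte_s - tcrossprod(t_o, fitc$p_orth[, i])
    }
    t_p <- as.numeric(Xte_s %*% fitc$w_star)
    tcv[test] <- t_p
    y_hat[test] <- fitc$y_mean + t_p * fitc$q
  }
  press <- sum((y - y_hat)^2)
  ss <- sum((y - mean(y))^2)
  structure(list(
    samples = tibble::tibble(sample_id = sid, y = y, fold = fold,
                             tcv = tcv, y_hat = y_hat),
    Q2 = 1 - press / ss, PRESS = press, SS = ss,
    k = k, A_orth = A_orth, scaling = scaling
  ), class = "opls_cv")
}

#' @export
print.opls_cv <- function(x, ...) {
  cat(sprintf("<opls_cv> %d-fold, A = 1 + %d + 0, Q2 = %.3f\n",
              x$k, x$A_orth, x$Q2))
  invisible(x)
}

#' @export
tidy.opls_cv <- function(x, ...) x$samples

#' @export
glance.opls_cv <- function(x, ...) {
  tibble::tibble(k = x$k, A_orth = x$A_orth, Q2 = x$Q2,
                 PRESS = x$PRESS, SS = x$SS)
}

#' CV-ANOVA significance test of a cross-validated model
#'
#' F-test comparing the variation explained by the cross-validated
#' predictions against the cross-validated residuals:
#' `F = ((SS - PRESS)/A) / (PRESS/(N - 1 - A))` with `A` the total number of
#' model components (one predictive plus the orthogonal ones) and `N` the
#' number of samples; the p-value is the upper tail of `F(A, N-1-A)`.  A
#' model with no predictive power (PRESS >= SS) gives F <= 0 and p = 1; a
#' vanishing PRESS gives a p-value floored at the smallest positive double
#' rather than exactly zero.
#'
#' @param cv An `opls_cv` object.
#' @param y Optional response; defaults to the one stored in `cv`.
#' @return The upper-tail probability (numeric scalar) with attributes
#'   `F`, `df1`, `df2`.
#' @export
cv_anova <- function(cv, y = NULL) {
  if (!inherits(cv, "opls_cv")) abort("`cv` must be an opls_cv object")
  y <- if (is.null(y)) cv$samples$y else as_binary(y)
  n <- length(y)
  a <- 1L + cv$A_orth
  df2 <- n - 1L - a
  if (df2 <= 0L) abort("too few samples for CV-ANOVA at this component count")
  f <- ((cv$SS - cv$PRESS) / a) / (cv$PRESS / df2)
  p <- if (!is.finite(f)) .Machine$double.xmin else if (f <= 0) 1 else {
    max(pf(f, a, df2, lower.tail = FALSE), .Machine$double.xmin)
  }
  structure(p, F = f, df1 = a, df2 = df2)
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Returns the smallest `A_orth` such that adding one more component fails
#' to improve Q2 by more than 0.01 (absolute); 0 is returnable and is the
#' outcome for data without structured y-orthogonal variation.
#'
#' @param table Unscaled feature table.
#' @param y Binary response.
#' @param max_orth Largest candidate count (>= 0).
#' @param k,scaling Passed to [cross_validate()].
#' @param min_gain Q2 improvement required to accept a further component.
#' @return Integer orthogonal-component count.
#' @export
select_orthogonal <- function(table, y, max_orth = 2L, k = 7L,
                              scaling = "uv", min_gain = 0.01) {
  max_orth <- check_count(max_orth, "max_orth", min = 0L)
  if (max_orth == 0L) return(0L)
  q2 <- purrr::map_dbl(0:max_orth, function(a) {
    cross_validate(table, y, A_orth = a, k = k, scaling = scaling)$Q2
  })
  for (a in 0:(max_orth - 1L)) {
    if (q2[a + 2L] - q2[a + 1L] <= min_gain) return(a)
  }
  max_orth
}
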