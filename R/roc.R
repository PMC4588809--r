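#' Area under the ROC curve by all-pairs counting
#'
#' `auc = (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)` over all
#' positive-negative pairs (the Mann-Whitney identity; half credit for
#' ties).  Orientation follows the scores as given — the model's sign
#' convention decides it, and values below 0.5 are reported as-is.
#'
#' @param scores Per-sample continuous scores.
#' @param labels Binary labels (1 = positive).
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary(labels)
  if (length(unique(labels)) < 2L) abort("both classes must be present")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC curve points
#'
#' Sweeps every distinct score threshold and returns the ordered
#' (false-positive rate, true-positive rate) path from (0,0) to (1,1);
#' both coordinates are non-decreasing.
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve_points <- function(scores, labels) {
  labels <- as_binary(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  tp <- purrr::map_int(thr, function(t) sum(scores >= t & labels == 1))
  fp <- purrr::map_int(thr, function(t) sum(scores >= t & labels == 0))
  tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fp / nn),
                 tpr = c(0, tp / np))
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples with replacement within each class, recomputes the AUC per
#' replicate, and reports the percentile 2.5/97.5 bounds.  When the classes
#' are perfectly separated with margin, every replicate has AUC 1 and the
#' interval degenerates to (1, 1).
#'
#' @inheritParams roc_auc
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
roc_ci <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  labels <- as_binary(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  aucs <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_boot), function(b) {
      i <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
      roc_auc(scores[i], labels[i])
    })
  })
  ci <- unname(quantile(aucs, c(0.025, 0.975), type = 7))
  c(lower = min(ci[1], 1), upper = min(ci[2], 1))
}

#' ROC evaluation of a cross-validated score pattern
#'
#' Computes the ROC curve, AUC and stratified bootstrap CI on the
#' cross-validated predictive scores (`tcv`) of an OPLS-DA model — never on
#' refit in-sample scores, so the evaluation carries no optimistic bias
#' from the fit itself.
#'
#' @param cv An `opls_cv` object.
#' @param labels Optional labels; defaults to those stored in `cv`.
#' @param n_boot,seed Passed to [roc_ci()].
#' @return A `roc_result`: `auc`, `ci`, `curve`, `n_boot`, `seed`,
#'   `scores`, `labels`.
#' @export
evaluate_pattern <- function(cv, labels = NULL, n_boot = 1000L, seed = 1L) {
  scores <- cv$samples$tcv
  labels <- if (is.null(labels)) cv$samples$y else as_binary(labels)
  roc_result(scores, labels, n_boot = n_boot, seed = seed)
}

#' @rdname evaluate_pattern
#' @param scores,labels Raw scores and binary labels (direct interface).
#' @export
roc_result <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  labels <- as_binary(labels)
  structure(list(
    auc = roc_auc(scores, labels),
    ci = roc_ci(scores, labels, n_boot = n_boot, seed = seed),
    curve = roc_curve_points(scores, labels),
    n_boot = n_boot, seed = seed, scores = scores, labels = labels
  ), class = "roc_result")
}

#' Format an AUC with its CI in "0.000 (0.000-0.000)" style
#' @param x A `roc_result`.
#' @return A string such as `"0.881 (0.791–0.970)"`.
#' @export
format_auc <- function(x) {
  sprintf("%.3f (%.3f–%.3f)", x$auc, x$ci["lower"], x$ci["upper"])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUROCC %s (%d bootstrap replicates)\n",
              format_auc(x), x$n_boot))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_lower = x$ci["lower"],
                 ci_upper = x$ci["upper"], n_boot = x$n_boot)
}

#' @rdname autoplot.opls_cv
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = paste("AUROCC", format_auc(object))) +
    ggplot2::theme_minimal()
}
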