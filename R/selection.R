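#' Select class-related features by the w* +/- 2 SD rule
#'
#' Computes the mean `m` and standard deviation `s` of the signed predictive
#' weights `w_star` across all features of a fitted model and selects the
#' features lying outside the band `m +/- 2 s`.  The rule is applied once —
#' no iterated reselect — and the per-feature p-values computed elsewhere
#' never gate it.
#'
#' @param model An `opls_model` fitted on all features (>= 3).
#' @return Integer indices (into the model's feature vector) of the
#'   selected features, named by feature id.
#' @export
select_features <- function(model) {
  w <- model$w_star
  if (length(w) < 3L) abort("model must carry at least 3 features")
  m <- mean(w); s <- sd(w)
  sel <- which(w < m - 2 * s | w > m + 2 * s)
  if (length(sel) == 0L) {
    abort(paste("the w* +/- 2 SD band selected no features;",
                "review the model or the threshold"))
  }
  sel
}

#' Refit the final OPLS-DA model on the selected features
#'
#' Reduces the table to the selected features, rescales, refits the model,
#' and reruns k-fold cross-validation and CV-ANOVA — producing the final
#' reported model (full fit plus cross-validated diagnostics).
#'
#' @param table Unscaled feature table (all features).
#' @param y Binary response.
#' @param selected Feature indices or names to keep (non-empty).
#' @param A_orth Orthogonal component count.
#' @param k Fold count.
#' @param scaling Scaling mode.
#' @return List with elements `model` (`opls_model`), `cv` (`opls_cv`) and
#'   `p_cvanova`.
#' @export
refit_final <- function(table, y, selected, A_orth = 0L, k = 7L,
                        scaling = "uv") {
  if (length(selected) == 0L) abort("`selected` must be non-empty")
  fc <- feature_cols(table)
  keep <- if (is.character(selected)) selected else fc[selected]
  sub <- table[, c(intersect(META_COLS, names(table)), keep)]
  fm <- feature_meta(table)
  attr(sub, "feature_meta") <- fm[fm$feature %in% keep, , drop = FALSE]
  model <- fit_opls(scale_features(sub, scaling), y, A_orth = A_orth)
  cv <- cross_validate(sub, y, A_orth = A_orth, k = k, scaling = scaling)
  list(model = model, cv = cv, p_cvanova = as.numeric(cv_anova(cv)))
}

#' Mann-Whitney U test
#'
#' `U` counts the pairs where a value of group A exceeds one of group B,
#' with half credit for ties.  The two-sided p-value is exact (full
#' enumeration of the rank distribution) when the smaller group has at most
#' 8 members and there are no ties; otherwise the normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return Tibble with `U` and `p`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- min(length(a), length(b)) <= 8L && !has_ties
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE, alternative = "two.sided")
  )
  tibble::tibble(U = as.numeric(ht$statistic), p = ht$p.value)
}

#' Direction of change of selected features
#'
#' Labels each selected feature "up" when the class-1 median exceeds the
#' class-0 median on the unscaled table, "down" when lower, and "ambiguous"
#' on an exact tie.
#'
#' @param table Unscaled feature table.
#' @param y Binary response.
#' @param selected Feature indices or names.
#' @return Tibble with `feature` and `direction`.
#' @export
annotate_direction <- function(table, y, selected) {
  y <- as_binary(y)
  X <- feature_matrix(table)
  keep <- if (is.character(selected)) selected else colnames(X)[selected]
  purrr::map_dfr(keep, function(f) {
    d <- median(X[y == 1, f]) - median(X[y == 0, f])
    tibble::tibble(feature = f,
                   direction = if (d > 0) "up" else if (d < 0) "down" else "ambiguous")
  })
}

#' Run the full selection stage and build a per-feature report
#'
#' Fits the initial all-feature model, applies the w* +/- 2 SD rule, refits
#' the final model with cross-validation and CV-ANOVA, and annotates every
#' selected feature with its direction of change and Mann-Whitney U test
#' (annotation only; no multiplicity correction by default, matching the
#' single-test-per-feature reporting convention, with Benjamini-Hochberg
#' available via `p_adjust`).
#'
#' @param table Unscaled feature table.
#' @param y Binary response.
#' @param A_orth Orthogonal component count.
#' @param k Fold count.
#' @param scaling Scaling mode.
#' @param alpha Significance threshold for the per-feature star.
#' @param p_adjust `"none"` (default) or `"BH"`.
#'
#' @details The cross-validated diagnostics of the *final* model are
#' computed after feature selection, exactly as the workflow reports them —
#' which means they inherit an optimistic selection bias: on pure-noise
#' data the refit of the largest-|w*| features looks significant.  The
#' *initial* (all-feature) cross-validation carries no such bias and is the
#' quantity whose type-I error is controlled; both are returned.
#'
#' @return A `selection_result`: `initial_model`, `initial_cv`,
#'   `p_initial`, `selected` (indices), `final_model`, `final_cv`,
#'   `p_cvanova`, and `per_feature` (tibble: feature, ri, putative_id,
#'   w_star, direction, U, p, significant).
#' @export
run_selection <- function(table, y, A_orth = 0L, k = 7L, scaling = "uv",
                          alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  y <- as_binary(y)
  initial <- fit_opls(scale_features(table, scaling), y, A_orth = A_orth)
  initial_cv <- cross_validate(table, y, A_orth = A_orth, k = k,
                               scaling = scaling)
  sel <- select_features(initial)
  final <- refit_final(table, y, sel, A_orth = A_orth, k = k, scaling = scaling)

  X <- feature_matrix(table)
  keep <- names(initial$w_star)[sel]
  dirs <- annotate_direction(table, y, keep)
  mw <- purrr::map_dfr(keep, function(f) mann_whitney(X[y == 1, f], X[y == 0, f]))
  pvals <- if (p_adjust == "BH") stats::p.adjust(mw$p, "BH") else mw$p
  fm <- feature_meta(table)
  per_feature <- tibble::tibble(
    feature = keep,
    w_star = as.numeric(initial$w_star[sel]),
    direction = dirs$direction,
    U = mw$U, p = pvals, significant = pvals < alpha
  ) %>%
    dplyr::left_join(fm, by = "feature") %>%
    dplyr::relocate(dplyr::any_of(c("feature", "ri", "putative_id")))

  structure(list(initial_model = initial, initial_cv = initial_cv,
                 p_initial = as.numeric(cv_anova(initial_cv)),
                 selected = sel,
                 final_model = final$model, final_cv = final$cv,
                 p_cvanova = final$p_cvanova, per_feature = per_feature),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d features selected (w* +/- 2 SD)\n",
              length(x$selected), length(x$initial_model$w_star)))
  print(x$final_model)
  cat(sprintf("  Q2 = %.3f, CV-ANOVA p = %.3g\n", x$final_cv$Q2, x$p_cvanova))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) x$per_feature

#' @export
glance.selection_result <- function(x, ...) {
  dplyr::bind_cols(glance(x$final_model),
                   tibble::tibble(Q2 = x$final_cv$Q2, p_cvanova = x$p_cvanova,
                                  Q2_initial = x$initial_cv$Q2,
                                  p_initial = x$p_initial,
                                  n_selected = length(x$selected)))
}
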