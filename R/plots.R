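#' Plot methods for model and evaluation objects
#'
#' `autoplot()` methods give the standard views of the workflow:
#' cross-validated score strip charts per class (`opls_cv`), PCA score
#' scatter with the Hotelling-T2 flags (`pca_overview`), and the ROC curve
#' (`roc_result`).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot.opls_cv
#' @export
autoplot.opls_cv <- function(object, ...) {
  d <- dplyr::mutate(object$samples, class = factor(.data$y))
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$tcv, colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.3,
                          colour = "black", linewidth = 0.3) +
    ggplot2::labs(x = "Class", y = "Cross-validated predictive score tcv[1]p",
                  subtitle = sprintf("Q2 = %.3f (%d-fold CV)",
                                     object$Q2, object$k)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot resolved elution profiles of one window
#'
#' @param features Resolved-feature tibble from [resolve_window()].
#' @param time Time axis of the window (seconds); defaults to point index.
#' @return A ggplot object with one line per resolved component.
#' @export
plot_resolved_profiles <- function(features, time = NULL) {
  d <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    prof <- features$elution_profile[[i]]
    tibble::tibble(component = features$component[i],
                   time = time %||% seq_along(prof), intensity = prof)
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$intensity,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Retention time (s)", y = "Normalized intensity",
                  colour = "Component") +
    ggplot2::theme_minimal()
}
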