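#' Run one two-class comparison end to end
#'
#' The modeling core of the workflow applied to a curated table: scale,
#' choose the orthogonal component count by cross-validation, fit the
#' initial all-feature OPLS-DA, select features by the w* +/- 2 SD rule,
#' refit the final model with k-fold cross-validation and CV-ANOVA, and
#' evaluate the cross-validated score pattern by ROC with a stratified
#' bootstrap CI.  Fully deterministic given the configuration and seed.
#'
#' @param table Curated, unscaled feature table.
#' @param y Binary response (0/1, logical, two-level factor), or `NULL` to
#'   use the table's `class` column.
#' @param name Comparison label carried into the report.
#' @param scaling Scaling mode.
#' @param k Fold count (default 7).
#' @param max_orth Cap for the orthogonal-component search.
#' @param alpha Per-feature annotation threshold.
#' @param n_boot,seed Bootstrap settings for the ROC CI.
#' @return A `comparison_result`: `name`, `selection` (see
#'   [run_selection()]), `roc` (`roc_result`), `A_orth`, plus the model
#'   statistics via [glance()].
#' @export
run_comparison <- function(table, y = NULL, name = "comparison",
                           scaling = "uv", k = 7L, max_orth = 0L,
                           alpha = 0.05, n_boot = 1000L, seed = 1L) {
  if (is.null(y)) {
    if (!"class" %in% names(table)) abort("no `y` given and no `class` column")
    y <- table$class
  }
  y <- as_binary(y)
  a_orth <- select_orthogonal(table, y, max_orth = max_orth, k = k,
                              scaling = scaling)
  selres <- run_selection(table, y, A_orth = a_orth, k = k, scaling = scaling,
                          alpha = alpha)
  roc <- evaluate_pattern(selres$final_cv, n_boot = n_boot, seed = seed)
  structure(list(name = name, selection = selres, roc = roc,
                 A_orth = a_orth, n = nrow(table), seed = seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<comparison_result> %s (n = %d)\n", x$name, x$n))
  cat(sprintf("  A = 1 + %d + 0, R2X = %.3g, R2Y = %.3g, Q2 = %.3g, p = %.3g\n",
              g$A_orth, g$R2X, g$R2Y, g$Q2, g$p_cvanova))
  cat(sprintf("  AUROCC %s; %d features selected\n",
              format_auc(x$roc), g$n_selected))
  invisible(x)
}

#' @export
tidy.comparison_result <- function(x, ...) {
  dplyr::mutate(x$selection$per_feature, comparison = x$name,
                .before = 1L)
}

#' @export
glance.comparison_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(comparison = x$name, n = x$n),
                   glance(x$selection),
                   tibble::tibble(auc = x$roc$auc,
                                  auc_lower = x$roc$ci[["lower"]],
                                  auc_upper = x$roc$ci[["upper"]]))
}

#' Run a configured study: curation plus a set of comparisons
#'
#' The configuration is a list (or a YAML file holding one) with elements:
#' \describe{
#'   \item{tables}{named list of feature-table file paths (see
#'     [read_feature_table()]), or in-memory tables.}
#'   \item{comparisons}{list of specs: `name`, `table` (name into
#'     `tables`), and either `classes` (always uses the table's `class`
#'     column) or `survival` (a preset name or `c(short_max, long_min)`);
#'     optional `scaling`, `k`, `max_orth`, `alpha`.}
#'   \item{seed}{integer; drives the bootstrap.}
#' }
#' Curation always precedes every comparison; no comparison ever sees an
#' excluded sample.
#'
#' @param config A list or path to a YAML file.
#' @param out_dir Optional directory; when given, the report is written as
#'   delimited text plus JSON (see [write_run_report()]).
#' @return A `run_report`: `curation` (named list of curation logs),
#'   `comparisons` (named list of `comparison_result`), `summary` (tibble),
#'   `seed`.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  bad <- setdiff(names(config), c("tables", "comparisons", "seed"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  }
  if (is.null(config$tables)) abort("config must list `tables`")
  seed <- config$seed %||% 1L

  tables <- purrr::imap(config$tables, function(t, nm) {
    if (is.character(t)) {
      if (!file.exists(t)) abort(sprintf("table file not found: %s", t))
      t <- read_feature_table(t)
    }
    t
  })
  curated <- purrr::map(tables, curate_table)

  comparisons <- list()
  for (spec in config$comparisons %||% list()) {
    if (is.null(spec$name) || is.null(spec$table)) {
      abort("each comparison needs `name` and `table` keys")
    }
    if (!spec$table %in% names(curated)) {
      abort(sprintf("comparison '%s' references unknown table '%s'",
                    spec$name, spec$table))
    }
    tbl <- curated[[spec$table]]$table
    if (!is.null(spec$survival)) {
      sv <- spec$survival
      grp <- if (is.character(sv)) {
        assign_survival_classes(tbl, preset = sv)
      } else {
        assign_survival_classes(tbl, short_max = sv[[1]], long_min = sv[[2]])
      }
      keep <- !is.na(grp$class)
      tbl <- tbl[keep, ]
      y <- grp$class[keep]
    } else {
      y <- tbl$class
    }
    comparisons[[spec$name]] <- run_comparison(
      tbl, y, name = spec$name,
      scaling = spec$scaling %||% "uv", k = spec$k %||% 7L,
      max_orth = spec$max_orth %||% 0L, alpha = spec$alpha %||% 0.05,
      seed = seed
    )
  }

  report <- structure(list(
    curation = purrr::map(curated, "log"),
    comparisons = comparisons,
    summary = purrr::map_dfr(comparisons, glance),
    seed = seed
  ), class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d comparison(s), seed %d\n",
              length(x$comparisons), x$seed))
  if (nrow(x$summary) > 0L) print(x$summary)
  invisible(x)
}
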