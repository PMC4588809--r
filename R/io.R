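#' Write / read a feature table as delimited text
#'
#' The table itself goes to `<path>` (tab-separated, samples in rows,
#' header row of feature ids); sample metadata (`sample_id`, `class`,
#' `survival_months`, ...) goes to the sidecar `<path>.meta.tsv`, and
#' per-feature metadata, when present, to `<path>.features.tsv`.
#'
#' @param table A feature table.
#' @param path Output path for the value matrix.
#' @return `read_feature_table()` returns the feature-table tibble with its
#'   `feature_meta` attribute restored.
#' @export
write_feature_table <- function(table, path) {
  X <- feature_matrix(table)
  df <- data.frame(sample_id = as.character(table$sample_id), X,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta_cols <- intersect(META_COLS, names(table))
  utils::write.table(as.data.frame(table)[, meta_cols, drop = FALSE],
                     paste0(path, ".meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  fm <- attr(table, "feature_meta")
  if (!is.null(fm)) {
    utils::write.table(as.data.frame(fm), paste0(path, ".features.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  meta_path <- paste0(path, ".meta.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE, check.names = FALSE)
  } else {
    data.frame(sample_id = df$sample_id)
  }
  X <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  fm <- NULL
  fm_path <- paste0(path, ".features.tsv")
  if (file.exists(fm_path)) {
    fm <- utils::read.table(fm_path, sep = "\t", header = TRUE,
                            check.names = FALSE)
  }
  as_feature_table(X, meta, feature_meta = fm)
}

#' Write / read a raw cube as delimited text
#'
#' A portable text serialization of a `gc_cube`: a header section with the
#' sample ids, time axis, m/z axis and retention-index markers, followed by
#' one long tab-separated block of intensities (sample, time index, m/z
#' index, intensity; zeros omitted).
#'
#' @param cube A `gc_cube`.
#' @param path Output path.
#' @return `read_cube()` returns the `gc_cube` (without ground truth).
#' @export
write_cube <- function(cube, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#samples\t", paste(cube$samples, collapse = "\t")),
    paste0("#time\t", paste(format(cube$time, digits = 12), collapse = "\t")),
    paste0("#mz\t", paste(cube$mz, collapse = "\t")),
    paste0("#ri_markers\t",
           paste(sprintf("%s:%s", format(cube$ri_markers$time, digits = 12),
                         cube$ri_markers$ri), collapse = "\t")),
    "sample\tt\tm\tintensity"
  ), con)
  nz <- which(cube$intensities != 0, arr.ind = TRUE)
  if (nrow(nz) > 0L) {
    writeLines(sprintf("%d\t%d\t%d\t%.10g", nz[, 1L], nz[, 2L], nz[, 3L],
                       cube$intensities[nz]), con)
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    strsplit(sub(paste0("^#", key, "\t"), "",
                 hdr[startsWith(hdr, paste0("#", key))]), "\t")[[1L]]
  }
  samples <- get("samples")
  time <- as.numeric(get("time"))
  mz <- as.integer(get("mz"))
  rim <- strsplit(get("ri_markers"), ":", fixed = TRUE)
  ri_markers <- tibble::tibble(
    time = as.numeric(purrr::map_chr(rim, 1L)),
    ri = as.numeric(purrr::map_chr(rim, 2L))
  )
  body <- lines[!startsWith(lines, "#")][-1L]
  arr <- array(0, dim = c(length(samples), length(time), length(mz)),
               dimnames = list(samples, NULL, mz))
  if (length(body) > 0L) {
    m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    arr[cbind(as.integer(m[, 1L]), as.integer(m[, 2L]), as.integer(m[, 3L]))] <-
      as.numeric(m[, 4L])
  }
  structure(list(samples = samples, time = time, mz = mz,
                 intensities = arr, ri_markers = ri_markers),
            class = "gc_cube")
}

#' Serialize / restore a run report
#'
#' Writes the study report as structured text: `summary.tsv` (one row per
#' comparison), per-comparison `features_<name>.tsv` (the Table-1-style
#' report), `curation_<table>.tsv` logs, cross-validated scores
#' `scores_<name>.tsv`, ROC curve points `roc_<name>.tsv`, and a
#' full-precision JSON snapshot `report.json` from which
#' [read_run_report()] rebuilds the numeric content.
#'
#' @param report A `run_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `read_run_report()` returns the parsed JSON structure (named
#'   lists/tibbles mirroring the report's numeric content).
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    as.data.frame(x), file.path(dir, f), sep = "\t", row.names = FALSE,
    quote = FALSE)
  tsv(report$summary, "summary.tsv")
  purrr::iwalk(report$curation, function(lg, nm) {
    tsv(lg, sprintf("curation_%s.tsv", nm))
  })
  purrr::iwalk(report$comparisons, function(cp, nm) {
    tsv(cp$selection$per_feature, sprintf("features_%s.tsv", nm))
    tsv(cp$selection$final_cv$samples, sprintf("scores_%s.tsv", nm))
    tsv(cp$roc$curve, sprintf("roc_%s.tsv", nm))
  })
  snapshot <- list(
    seed = report$seed,
    summary = report$summary,
    curation = purrr::map(report$curation, identity),
    comparisons = purrr::map(report$comparisons, function(cp) {
      list(name = cp$name, A_orth = cp$A_orth, n = cp$n,
           per_feature = cp$selection$per_feature,
           scores = cp$selection$final_cv$samples,
           Q2 = cp$selection$final_cv$Q2,
           p_cvanova = cp$selection$p_cvanova,
           auc = cp$roc$auc, ci = as.list(cp$roc$ci),
           curve = cp$roc$curve)
    })
  )
  jsonlite::write_json(snapshot, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
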