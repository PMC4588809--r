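#' Build a spectral library
#'
#' A spectral library is a tibble with one entry per compound: `name`
#' (unique), `ri` (retention index) and `spectrum` (list-column of
#' non-negative, unit-sum intensity vectors over a shared m/z grid).
#'
#' @param name Character vector of unique compound names.
#' @param ri Numeric retention indices.
#' @param spectra List of non-negative numeric vectors (one per entry);
#'   normalized to unit sum on construction.
#' @return A `spectral_library` tibble.
#' @export
spectral_library <- function(name, ri, spectra) {
  if (anyDuplicated(name)) abort("library names must be unique")
  if (length(name) != length(ri) || length(name) != length(spectra)) {
    abort("`name`, `ri` and `spectra` must have equal length")
  }
  spectra <- purrr::map(spectra, function(s) {
    if (any(s < 0)) abort("library spectra must be non-negative")
    if (sum(s) > 0) s / sum(s) else s
  })
  out <- tibble::tibble(name = name, ri = as.numeric(ri), spectrum = spectra)
  class(out) <- c("spectral_library", class(out))
  out
}

#' Match resolved features against a spectral library
#'
#' For each feature, the best cosine similarity among library entries whose
#' retention index lies within `ri_tol` of the feature's is computed; the
#' identity is assigned only when the score reaches `min_score`, otherwise
#' the feature stays unidentified (unidentified features are kept, never
#' dropped).
#'
#' @param features Resolved-feature tibble with `retention_index` assigned.
#' @param library A [spectral_library()].
#' @param min_score Cosine threshold for accepting an identity.
#' @param ri_tol Retention-index tolerance gating the candidate set.
#' @return `features` with `putative_id` (character, `NA` when unmatched)
#'   and `match_score` columns.
#' @export
match_library <- function(features, library, min_score = 0.8, ri_tol = 30) {
  if (nrow(library) == 0L) abort("library is empty")
  res <- purrr::map(seq_len(nrow(features)), function(i) {
    cand <- which(abs(library$ri - features$retention_index[i]) <= ri_tol)
    if (length(cand) == 0L) return(list(id = NA_character_, score = NA_real_))
    scores <- purrr::map_dbl(cand, function(j) {
      cosine_sim(features$spectrum[[i]], library$spectrum[[j]])
    })
    best <- which.max(scores)
    if (scores[best] >= min_score) {
      list(id = library$name[cand[best]], score = scores[best])
    } else {
      list(id = NA_character_, score = scores[best])
    }
  })
  features$putative_id <- purrr::map_chr(res, "id")
  features$match_score <- purrr::map_dbl(res, "score")
  features
}

#' Normalize feature areas by internal standards
#'
#' Divides each sample's feature areas by the geometric mean of that
#' sample's internal-standard areas, then drops the IS features from the
#' output.  Samples in which any internal standard has a non-positive area
#' cannot be normalized (the signature of a failed derivatization) and are
#' excluded, with the exclusions recorded in the `excluded` attribute.
#'
#' @param features Resolved-feature tibble (with `putative_id` if IS are
#'   identified by library match rather than by component id).
#' @param is_names Identifiers of the internal standards; matched against
#'   `putative_id` where present, else against `component`.
#' @return A feature-table tibble (sample_id + feature columns named by
#'   component id) with attributes `feature_meta` (component, ri,
#'   putative_id) and `excluded` (tibble sample_id/reason).
#' @export
normalize_by_is <- function(features, is_names) {
  ids <- if ("putative_id" %in% names(features)) {
    dplyr::coalesce(features$putative_id, features$component)
  } else features$component
  is_idx <- which(ids %in% is_names)
  if (length(is_idx) == 0L) abort("no internal-standard features found")
  A <- areas_matrix(features)
  is_A <- A[, is_idx, drop = FALSE]
  bad <- apply(is_A, 1L, function(v) any(!is.finite(v) | v <= 0))
  excluded <- tibble::tibble(sample_id = rownames(A)[bad],
                             reason = "nonpositive internal-standard area")
  keep <- !bad
  gm <- exp(rowMeans(log(is_A[keep, , drop = FALSE])))
  norm <- A[keep, -is_idx, drop = FALSE] / gm
  meta <- tibble::tibble(sample_id = rownames(A)[keep])
  fm <- tibble::tibble(
    feature = features$component[-is_idx],
    ri = if ("retention_index" %in% names(features)) {
      features$retention_index[-is_idx]
    } else NA_real_,
    putative_id = if ("putative_id" %in% names(features)) {
      features$putative_id[-is_idx]
    } else NA_character_
  )
  out <- as_feature_table(norm, meta, feature_meta = fm)
  attr(out, "excluded") <- excluded
  out
}

#' Write / read a spectral library as delimited text
#'
#' Format: tab-separated `name`, `ri`, `spectrum`, the latter a
#' space-separated list of `mz:intensity` pairs on an integer m/z grid.
#'
#' @param library A [spectral_library()]; `mz` the shared m/z grid.
#' @param path File path.
#' @return `read_spectral_library()` returns list(library, mz).
#' @export
write_spectral_library <- function(library, mz, path) {
  lines <- purrr::map_chr(seq_len(nrow(library)), function(i) {
    s <- library$spectrum[[i]]
    nz <- which(s > 0)
    paste(library$name[i], format(library$ri[i], digits = 10),
          paste(sprintf("%d:%.8g", mz[nz], s[nz]), collapse = " "),
          sep = "\t")
  })
  writeLines(c("name\tri\tspectrum", lines), path)
  invisible(path)
}

#' @rdname write_spectral_library
#' @export
read_spectral_library <- function(path) {
  lines <- readLines(path)[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pairs <- purrr::map(parts, function(p) {
    kv <- strsplit(strsplit(p[3L], " ", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    tibble::tibble(mz = as.integer(purrr::map_chr(kv, 1L)),
                   int = as.numeric(purrr::map_chr(kv, 2L)))
  })
  mz <- sort(unique(unlist(purrr::map(pairs, "mz"))))
  mz <- seq(min(mz), max(mz))
  spectra <- purrr::map(pairs, function(pp) {
    s <- numeric(length(mz))
    s[match(pp$mz, mz)] <- pp$int
    s
  })
  list(
    library = spectral_library(purrr::map_chr(parts, 1L),
                               as.numeric(purrr::map_chr(parts, 2L)), spectra),
    mz = mz
  )
}

#' Derive a spectral library from simulation ground truth
#'
#' Convenience for closed-loop tests: turns the true component spectra and
#' retention indices of a simulated cube into a library, so that resolved
#' features can be re-identified.
#'
#' @param cube A simulated `gc_cube`.
#' @return A [spectral_library()].
#' @export
truth_library <- function(cube) {
  tr <- ground_truth(cube)
  ri <- purrr::map_dbl(tr$components$center, function(ct) {
    stats::approx(cube$ri_markers$time, cube$ri_markers$ri, xout = ct,
                  rule = 2L)$y
  })
  spectral_library(tr$components$component, ri,
                   purrr::map(seq_len(nrow(tr$components)),
                              function(j) tr$spectra[j, ]))
}
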