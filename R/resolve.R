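#' Baseline correction by rolling minimum
#'
#' Estimates, per sample and per m/z channel, a slowly varying baseline by a
#' morphological opening (rolling minimum then rolling maximum, which tracks
#' drifting baselines without biasing them low) followed by a
#' moving-average smooth, subtracts it and clips at zero.  The total ion
#' current is never increased.
#'
#' @param cube A `gc_cube`.
#' @param window_length Rolling-window length in time points; odd, >= 3, and
#'   comfortably wider than a chromatographic peak at base.
#' @return The corrected `gc_cube`.
#' @export
baseline_correct <- function(cube, window_length = 21L) {
  wl <- check_count(window_length, "window_length", min = 3L)
  if (wl %% 2L == 0L) abort("`window_length` must be odd")
  n_t <- length(cube$time)
  if (wl > n_t) abort("`window_length` exceeds the time axis")
  x <- cube$intensities
  for (s in seq_along(cube$samples)) {
    m <- x[s, , ]
    base <- apply(m, 2L, function(v) roll_mean(roll_max(roll_min(v, wl), wl), wl))
    m <- m - base
    m[m < 0] <- 0
    x[s, , ] <- m
  }
  cube$intensities <- x
  cube
}

#' Segment a cube into time windows at total-ion-current minima
#'
#' Boundaries are placed at the lowest local minima of the smoothed mean
#' total-ion-current curve, subject to a minimum window width, so that
#' windows tile the time axis.  Index convention is half-open `[start, end)`
#' with 0-based indices into the time axis.
#'
#' @param cube A `gc_cube`.
#' @param n_windows Number of windows (>= 1).
#' @param min_width Minimum window width in time points; default half the
#'   average window width.
#' @return A list of windows, each a list with `index`, `start`, `end`
#'   (0-based half-open), `time` (the time slice) and `tensor`
#'   (sample x time x m/z array restricted to the slice).
#' @export
segment_windows <- function(cube, n_windows, min_width = NULL) {
  nw <- check_count(n_windows, "n_windows")
  n_t <- length(cube$time)
  if (is.null(min_width)) min_width <- max(5L, floor(n_t / (2L * nw)))
  if (nw * min_width > n_t) {
    abort("`n_windows` too large for the time axis at this minimum width")
  }
  cuts <- integer(0)                         # 0-based boundary positions
  if (nw > 1L) {
    tic <- apply(cube$intensities, 2L, sum)  # summed over samples and m/z
    tic <- roll_mean(tic, 5L)
    i <- 2:(n_t - 1L)
    cand <- i[tic[i] <= tic[i - 1L] & tic[i] <= tic[i + 1L]]
    cand <- cand[order(tic[cand])]
    ok <- function(pos, cuts) {
      all(abs(pos - c(0L, cuts, n_t)) >= min_width)
    }
    for (pos in cand - 1L) {                 # to 0-based
      if (length(cuts) == nw - 1L) break
      if (ok(pos, cuts)) cuts <- c(cuts, pos)
    }
    # deterministic fallback: bisect the largest remaining gaps
    while (length(cuts) < nw - 1L) {
      b <- sort(c(0L, cuts, n_t))
      gaps <- diff(b)
      g <- which.max(gaps)
      pos <- b[g] + gaps[g] %/% 2L
      if (!ok(pos, cuts)) {
        abort("`n_windows` too large for the time axis at this minimum width")
      }
      cuts <- c(cuts, pos)
    }
    cuts <- sort(cuts)
  }
  bounds <- c(0L, cuts, n_t)
  purrr::map(seq_len(nw), function(w) {
    idx <- (bounds[w] + 1L):bounds[w + 1L]
    list(index = w, start = bounds[w], end = bounds[w + 1L],
         time = cube$time[idx],
         tensor = cube$intensities[, idx, , drop = FALSE],
         samples = cube$samples, mz = cube$mz)
  })
}

# purest-variable initialization: pick k m/z channels whose columns are
# maximally mutually independent (iterative residual-norm maximization)
purest_columns <- function(D, k) {
  R <- D
  chosen <- integer(0)
  for (i in seq_len(k)) {
    nrm <- colSums(R^2)
    nrm[chosen] <- -1
    j <- which.max(nrm)
    chosen <- c(chosen, j)
    v <- R[, j]
    if (sum(v^2) > 0) {
      R <- R - v %*% (crossprod(v, R) / sum(v^2))
    }
  }
  chosen
}

#' Resolve one time window into pure elution profiles and spectra
#'
#' Factorizes the sample-concatenated window matrix by alternating least
#' squares under non-negativity (both factors) and unimodality (per-sample
#' elution segments), initialized from the purest m/z channels.  The rank is
#' the smallest number of singular values explaining >= 99% of the variance,
#' capped at `max_components`.  Per-sample areas are trapezoidal integrals
#' of each sample's resolved elution segment; with unit-sum spectra these
#' are on the scale of the underlying component amounts.
#'
#' @param window One window as produced by [segment_windows()].
#' @param max_components Rank cap (>= 1).
#' @param tol Relative-fit convergence threshold.
#' @param max_iter Iteration cap; non-convergence flags the result rather
#'   than failing.
#' @return A tibble of resolved features with columns `component`, `window`,
#'   `apex_time`, `converged`, and list-columns `elution_profile` (unit
#'   maximum, over window time points), `spectrum` (unit sum, over m/z) and
#'   `areas` (named per-sample vector).  Zero rows for an all-zero window.
#' @export
resolve_window <- function(window, max_components = 5L, tol = 1e-9,
                           max_iter = 500L) {
  kmax <- check_count(max_components, "max_components")
  tens <- window$tensor
  ns <- dim(tens)[1L]; nt <- dim(tens)[2L]; nmz <- dim(tens)[3L]
  D <- matrix(aperm(tens, c(2L, 1L, 3L)), ns * nt, nmz)  # samples stacked in time
  if (all(D == 0)) return(empty_features())
  if (any(D < 0)) abort("window tensor must be non-negative")

  sv <- svd(D, nu = 0L, nv = 0L)$d
  k <- min(which(cumsum(sv^2) / sum(sv^2) >= 0.99), kmax)

  C <- D[, purest_columns(D, k), drop = FALSE]
  S <- matrix(0, k, nmz)
  lam <- 1e-12 * sum(D^2)
  fit_old <- Inf
  converged <- FALSE
  ssD <- sum(D^2)
  for (it in seq_len(max_iter)) {
    S <- solve(crossprod(C) + lam * diag(k), crossprod(C, D))
    S[S < 0] <- 0
    rs <- rowSums(S)
    rs[rs == 0] <- 1
    S <- S / rs                                      # unit-sum spectra
    C <- D %*% t(S) %*% solve(tcrossprod(S) + lam * diag(k))
    C[C < 0] <- 0
    for (j in seq_len(k)) {
      for (s in seq_len(ns)) {
        seg <- (s - 1L) * nt + seq_len(nt)
        C[seg, j] <- enforce_unimodal(C[seg, j])
      }
    }
    fit <- sum((D - C %*% S)^2) / ssD
    if (is.finite(fit_old) && abs(fit_old - fit) < tol) { converged <- TRUE; break }
    fit_old <- fit
  }

  win_idx <- window$index
  win_time <- window$time
  win_samples <- window$samples
  purrr::map_dfr(seq_len(k), function(j) {
    cj <- matrix(C[, j], nt, ns)                     # time x sample segments
    areas <- apply(cj, 2L, function(v) pracma::trapz(win_time, v))
    names(areas) <- win_samples
    mean_prof <- rowMeans(cj)
    mx <- max(mean_prof)
    tibble::tibble(
      component = sprintf("W%02dF%d", win_idx, j),
      window = win_idx,
      apex_time = win_time[which.max(mean_prof)],
      converged = converged,
      elution_profile = list(if (mx > 0) mean_prof / mx else mean_prof),
      spectrum = list(S[j, ]),
      areas = list(areas)
    )
  })
}

empty_features <- function() {
  tibble::tibble(component = character(), window = integer(),
                 apex_time = numeric(), converged = logical(),
                 elution_profile = list(), spectrum = list(), areas = list())
}

#' Per-sample area matrix of a resolved-feature tibble
#' @param features Tibble from [resolve_window()] / [resolve_cube()].
#' @return Numeric matrix, samples x features.
#' @export
areas_matrix <- function(features) {
  m <- do.call(cbind, features$areas)
  colnames(m) <- features$component
  m
}

#' Assign retention indices by linear interpolation between markers
#'
#' Each feature's apex time is interpolated linearly between the bracketing
#' retention-index markers.  Apexes outside the marker range are linearly
#' extrapolated and flagged.
#'
#' @param features Resolved-feature tibble.
#' @param ri_markers Tibble with `time` and `ri` columns, both strictly
#'   increasing; at least 2 rows.
#' @return `features` with `retention_index` and `ri_extrapolated` columns.
#' @export
assign_retention_index <- function(features, ri_markers) {
  if (nrow(ri_markers) < 2L) abort("need at least 2 retention-index markers")
  if (any(diff(ri_markers$time) <= 0) || any(diff(ri_markers$ri) <= 0)) {
    abort("`ri_markers` must be strictly increasing in time and ri")
  }
  f <- stats::approxfun(ri_markers$time, ri_markers$ri, rule = 2L)
  slope_lo <- diff(ri_markers$ri[1:2]) / diff(ri_markers$time[1:2])
  slope_hi <- diff(tail(ri_markers$ri, 2L)) / diff(tail(ri_markers$time, 2L))
  interp <- function(t) {
    if (t < ri_markers$time[1L]) {
      ri_markers$ri[1L] + slope_lo * (t - ri_markers$time[1L])
    } else if (t > tail(ri_markers$time, 1L)) {
      tail(ri_markers$ri, 1L) + slope_hi * (t - tail(ri_markers$time, 1L))
    } else f(t)
  }
  features$retention_index <- purrr::map_dbl(features$apex_time, interp)
  features$ri_extrapolated <- features$apex_time < ri_markers$time[1L] |
    features$apex_time > tail(ri_markers$time, 1L)
  features
}

#' Merge split components across adjacent windows
#'
#' Automatic stand-in for manual curation of split peaks: two components in
#' adjacent windows are merged when their spectra agree (cosine > 0.98) and
#' their apexes are within two time points of each other.  Areas are summed;
#' the earlier component's profile and spectrum are kept.
#'
#' @param features Resolved-feature tibble (RI already assigned or not).
#' @param dt Time-axis sampling interval (seconds).
#' @return The merged tibble.
#' @export
merge_split_features <- function(features, dt) {
  if (nrow(features) < 2L) return(features)
  drop <- rep(FALSE, nrow(features))
  ord <- order(features$apex_time)
  f <- features[ord, ]
  for (i in seq_len(nrow(f) - 1L)) {
    if (drop[i]) next
    for (j in (i + 1L):nrow(f)) {
      if (drop[j]) next
      if (abs(f$window[j] - f$window[i]) != 1L) next
      if (abs(f$apex_time[j] - f$apex_time[i]) > 2 * dt) next
      if (cosine_sim(f$spectrum[[i]], f$spectrum[[j]]) > 0.98) {
        f$areas[[i]] <- f$areas[[i]] + f$areas[[j]]
        drop[j] <- TRUE
      }
    }
  }
  f[!drop, ]
}

#' Resolve a whole cube: baseline, segmentation, per-window MCR-ALS
#'
#' Convenience wrapper running [baseline_correct()], [segment_windows()],
#' [resolve_window()] per window, retention-index assignment and the
#' split-peak merge rule.
#'
#' @param cube A `gc_cube`.
#' @param n_windows Number of time windows.
#' @param baseline_window Odd window length for baseline correction; `NULL`
#'   skips the step (synthetic cubes without drift do not need it).
#' @param max_components,tol,max_iter Passed to [resolve_window()].
#' @return Resolved-feature tibble with retention indices.
#' @export
resolve_cube <- function(cube, n_windows, baseline_window = NULL,
                         max_components = 5L, tol = 1e-9, max_iter = 500L) {
  if (!is.null(baseline_window)) cube <- baseline_correct(cube, baseline_window)
  wins <- segment_windows(cube, n_windows)
  feats <- purrr::map_dfr(wins, resolve_window, max_components = max_components,
                          tol = tol, max_iter = max_iter)
  if (nrow(feats) == 0L) return(feats)
  feats <- assign_retention_index(feats, cube$ri_markers)
  merge_split_features(feats, dt = diff(cube$time[1:2]))
}
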