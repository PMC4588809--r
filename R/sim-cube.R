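#' Simulate a raw GC-TOFMS data cube with known ground truth
#'
#' Generates a three-dimensional intensity array (sample x retention time x
#' m/z) built from Gaussian elution peaks with fixed sparse mass spectra,
#' organised in time windows of co-eluting components — the structure that
#' windowed multivariate curve resolution is designed to take apart.
#' Optional internal-standard (IS) components have class-independent
#' nominal areas; when present, every sample's whole signal is additionally
#' multiplied by a sample-specific log-normal recovery factor, so that IS
#' normalization has real instrumental variation to remove.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_windows Number of time windows.
#' @param components_per_window Analyte components co-eluting per window.
#' @param n_is Number of internal-standard components (placed one per
#'   window, round-robin); must not exceed the number of analyte components.
#' @param overlap Fraction 0-1 controlling co-elution: adjacent peak centers
#'   in a window are `4 * sigma * (1 - overlap)` apart (0 = baseline
#'   separated, 0.5 = centers two sigma apart, 1 = complete co-elution).
#' @param snr Signal-to-noise ratio at the peak apex: Gaussian noise with SD
#'   proportional to the local signal (plus a 1%-of-maximum dark floor),
#'   so `snr` is the apex intensity over its noise SD.  `Inf` disables
#'   noise.
#' @param baseline_drift Amplitude (detector units) of a slow per-channel
#'   sinusoidal baseline; 0 disables it.
#' @param seed Integer seed; identical seeds give bit-identical cubes.
#' @param points_per_window Time points per window (default 30).
#' @param n_mz Number of integer m/z bins (default 80, capped at 500).
#' @param dt Sampling interval in seconds (default 0.5).
#' @return A `gc_cube` object: list with `samples`, `time` (seconds,
#'   strictly increasing), `mz` (integer bins), `intensities`
#'   (sample x time x m/z array, >= 0), `ri_markers` (tibble of time/ri
#'   anchor pairs), carrying a `truth` attribute with `components` (tibble:
#'   component, window, is_standard, center, sigma), `spectra` (component x
#'   m/z, unit-sum rows), `true_areas` and `observed_areas` (sample x
#'   component), `recovery`, `class_labels`.
#' @examples
#' cube <- simulate_cube(n_samples = 4, n_windows = 2,
#'                       components_per_window = 2, seed = 1)
#' dim(cube$intensities)
#' @export
simulate_cube <- function(n_samples = 20L,
                          n_windows = 4L,
                          components_per_window = 3L,
                          n_is = 0L,
                          overlap = 0.3,
                          snr = 100,
                          baseline_drift = 0,
                          seed = 1L,
                          points_per_window = 30L,
                          n_mz = 80L,
                          dt = 0.5) {
  ns <- check_count(n_samples, "n_samples", min = 2L)
  nw <- check_count(n_windows, "n_windows")
  cpw <- check_count(components_per_window, "components_per_window")
  nis <- check_count(n_is, "n_is", min = 0L)
  ov <- check_fraction(overlap, "overlap")
  if (!is.numeric(snr) || snr <= 0) abort("`snr` must be > 0")
  if (baseline_drift < 0) abort("`baseline_drift` must be >= 0")
  n_mz <- check_count(n_mz, "n_mz", min = 10L)
  if (n_mz > 500L) abort("`n_mz` must be <= 500")
  ppw <- check_count(points_per_window, "points_per_window", min = 10L)
  if (nis > nw * cpw) abort("`n_is` must not exceed the number of analyte components")

  n_t <- nw * ppw
  time <- 300 + dt * (seq_len(n_t) - 1L)
  mz <- 50L + seq_len(n_mz) - 1L
  sigma <- 1.5 * dt

  # component layout: analyte cluster centered mid-window, IS offset early
  comp <- list()
  for (w in seq_len(nw)) {
    t0 <- time[(w - 1L) * ppw + 1L]
    mid <- t0 + dt * (ppw - 1L) / 2
    sep <- 4 * sigma * (1 - ov)
    centers <- mid + (seq_len(cpw) - (cpw + 1) / 2) * sep
    comp[[w]] <- tibble::tibble(
      component = sprintf("W%02dC%d", w, seq_len(cpw)),
      window = w, is_standard = FALSE, center = centers, sigma = sigma
    )
  }
  comp <- dplyr::bind_rows(comp)
  if (nis > 0L) {
    is_w <- rep(seq_len(nw), length.out = nis)
    is_tbl <- tibble::tibble(
      component = sprintf("IS%02d", seq_len(nis)),
      window = is_w, is_standard = TRUE,
      center = time[(is_w - 1L) * ppw + 1L] + 5 * dt, sigma = sigma
    )
    comp <- dplyr::bind_rows(comp, is_tbl)
  }
  k <- nrow(comp)

  withr::with_seed(seed, {
    # sparse unit-sum spectra, 8 fragments each
    spectra <- matrix(0, k, n_mz, dimnames = list(comp$component, mz))
    for (j in seq_len(k)) {
      frag <- sample.int(n_mz, 8L)
      spectra[j, frag] <- runif(8L, 0.2, 1)
      spectra[j, ] <- spectra[j, ] / sum(spectra[j, ])
    }
    true_areas <- matrix(
      rlnorm(ns * k, meanlog = log(50), sdlog = 0.25), ns, k,
      dimnames = list(NULL, comp$component)
    )
    if (nis > 0L) {
      true_areas[, comp$is_standard] <-
        matrix(rlnorm(ns * nis, log(50), 0.05), ns, nis)
      recovery <- rlnorm(ns, 0, 0.2)
    } else {
      recovery <- rep(1, ns)
    }
    observed_areas <- true_areas * recovery

    # unit-integral Gaussian elution profiles
    profiles <- matrix(0, k, n_t)
    for (j in seq_len(k)) {
      g <- exp(-0.5 * ((time - comp$center[j]) / comp$sigma[j])^2)
      profiles[j, ] <- g / pracma::trapz(time, g)
    }

    cube <- array(0, dim = c(ns, n_t, n_mz),
                  dimnames = list(sprintf("S%03d", seq_len(ns)), NULL, mz))
    for (s in seq_len(ns)) {
      m <- t(profiles) %*% (spectra * observed_areas[s, ])
      cube[s, , ] <- m
    }

    if (baseline_drift > 0) {
      phase <- runif(ns, 0, 2 * pi)
      for (s in seq_len(ns)) {
        b <- baseline_drift * (0.5 + 0.5 * sin(2 * pi * (time - time[1L]) /
                                                 (max(time) - time[1L]) + phase[s]))
        cube[s, , ] <- cube[s, , ] + b
      }
    }
    if (is.finite(snr)) {
      # detector-like noise: proportional to signal plus a small dark floor,
      # so the stated SNR holds at the peak apex
      noise_sd <- (cube + 0.01 * max(cube)) / snr
      cube <- cube + array(rnorm(length(cube), 0, 1), dim = dim(cube)) * noise_sd
      cube[cube < 0] <- 0
    }
  })

  ri_markers <- tibble::tibble(
    time = time[c(seq(1L, n_t, by = ppw), n_t)],
    ri = 1000 + 100 * (0:nw)
  )

  out <- structure(
    list(samples = sprintf("S%03d", seq_len(ns)), time = time, mz = mz,
         intensities = cube, ri_markers = ri_markers,
         points_per_window = ppw),
    class = "gc_cube"
  )
  attr(out, "truth") <- list(
    components = comp, spectra = spectra,
    true_areas = true_areas, observed_areas = observed_areas,
    recovery = recovery,
    class_labels = rep_len(c(0L, 1L), ns),
    informative_features = integer(0), effect_size = 0
  )
  out
}

#' @export
print.gc_cube <- function(x, ...) {
  cat(sprintf("<gc_cube> %d samples x %d time points x %d m/z bins\n",
              length(x$samples), length(x$time), length(x$mz)))
  cat(sprintf("  time %.1f-%.1f s, %d retention-index markers\n",
              min(x$time), max(x$time), nrow(x$ri_markers)))
  invisible(x)
}

#' Tidy a cube into a long tibble of intensities
#' @param x A `gc_cube`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `time`, `mz`, `intensity`.
#' @export
tidy.gc_cube <- function(x, ...) {
  d <- dim(x$intensities)
  tibble::tibble(
    sample_id = rep(x$samples, times = d[2L] * d[3L]),
    time = rep(rep(x$time, each = d[1L]), times = d[3L]),
    mz = rep(x$mz, each = d[1L] * d[2L]),
    intensity = as.vector(x$intensities)
  )
}
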