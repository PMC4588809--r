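test_that("a flat chromatogram is removed entirely by baseline correction", {
  n_t <- 60; n_mz <- 5
  arr <- array(3.7, dim = c(1, n_t, n_mz))
  cube <- make_cube(arr, time = seq_len(n_t), mz = 50:54)
  out <- baseline_correct(cube, window_length = 11)
  expect_true(all(out$intensities == 0))
})

test_that("baseline correction preserves a narrow peak and never raises the TIC", {
  n_t <- 200
  time <- seq_len(n_t)
  peak <- 100 * exp(-0.5 * ((time - 100) / 3)^2)
  ramp <- 0.05 * time                      # drifting baseline
  arr <- array(0, dim = c(1, n_t, 2))
  arr[1, , 1] <- peak
  arr[1, , 2] <- peak + ramp
  cube <- make_cube(arr, time = time, mz = 50:51)
  out <- baseline_correct(cube, window_length = 31)
  # apex height within 5% on the clean channel
  expect_lt(abs(max(out$intensities[1, , 1]) - 100) / 100, 0.05)
  # area of the ramp-corrected peak within 10% of truth
  truth_area <- pracma::trapz(time, peak)
  got_area <- pracma::trapz(time, out$intensities[1, , 2])
  expect_lt(abs(got_area - truth_area) / truth_area, 0.10)
  # total ion current never increased
  expect_true(all(out$intensities <= cube$intensities + 1e-12))
})

test_that("baseline correction validates its window length", {
  cube <- make_cube(array(1, dim = c(1, 20, 2)), time = 1:20, mz = 50:51)
  expect_error(baseline_correct(cube, 4), "odd")
  expect_error(baseline_correct(cube, 31), "time axis")
})

test_that("a single window spans the full axis half-open", {
  cube <- simulate_cube(n_samples = 2, n_windows = 2, components_per_window = 1,
                        snr = Inf, seed = 1)
  w <- segment_windows(cube, 1)
  expect_length(w, 1)
  expect_identical(w[[1]]$start, 0L)
  expect_identical(w[[1]]$end, length(cube$time))
})

test_that("a boundary between two separated peaks falls strictly between their apexes", {
  cube <- simulate_cube(n_samples = 3, n_windows = 2, components_per_window = 1,
                        snr = 100, seed = 2)
  tr <- ground_truth(cube)
  wins <- segment_windows(cube, 2)
  cut_time <- cube$time[wins[[1]]$end]     # first time point of window 2
  expect_gt(cut_time, min(tr$components$center))
  expect_lt(cut_time, max(tr$components$center))
})

test_that("windows tile the axis and isolate one peak cluster each at full scale", {
  nw <- 64
  cube <- simulate_cube(n_samples = 3, n_windows = nw,
                        components_per_window = 1, snr = 100, seed = 6)
  tr <- ground_truth(cube)
  wins <- segment_windows(cube, nw)
  expect_identical(vapply(wins, `[[`, integer(1), "start")[1], 0L)
  expect_identical(vapply(wins, `[[`, integer(1), "end")[nw],
                   length(cube$time))
  starts <- vapply(wins, `[[`, integer(1), "start")
  ends <- vapply(wins, `[[`, integer(1), "end")
  expect_identical(starts[-1], ends[-nw])  # no gaps, no overlap
  counts <- vapply(wins, function(w) {
    sum(tr$components$center >= w$time[1] &
          tr$components$center <= w$time[length(w$time)])
  }, integer(1))
  expect_true(all(counts == 1L))
})

test_that("a noise-free single-component window is resolved exactly", {
  cube <- simulate_cube(n_samples = 2, n_windows = 1, components_per_window = 1,
                        n_is = 0, overlap = 0, snr = Inf, baseline_drift = 0,
                        seed = 1)
  tr <- ground_truth(cube)
  rf <- resolve_window(segment_windows(cube, 1)[[1]])
  expect_identical(nrow(rf), 1L)
  expect_equal(cos_sim(rf$spectrum[[1]], tr$spectra[1, ]), 1, tolerance = 1e-6)
  expect_equal(unname(rf$areas[[1]]), unname(tr$observed_areas[, 1]),
               tolerance = 1e-4)
})

test_that("two half-overlapping components are recovered at snr 100", {
  cube <- simulate_cube(n_samples = 10, n_windows = 1,
                        components_per_window = 2, n_is = 0, overlap = 0.5,
                        snr = 100, baseline_drift = 0, seed = 1)
  tr <- ground_truth(cube)
  rf <- resolve_window(segment_windows(cube, 1)[[1]])
  expect_identical(nrow(rf), 2L)
  asg <- best_assignment(rf$spectrum, tr$spectra)
  expect_true(all(asg$cosines > 0.99))
  A <- areas_matrix(rf)
  for (i in 1:2) {
    rel <- abs(A[, i] - tr$observed_areas[, asg$assignment[i]]) /
      tr$observed_areas[, asg$assignment[i]]
    expect_true(all(rel < 0.05))
  }
})

test_that("three co-eluting components give a perfect cosine matching", {
  cube <- simulate_cube(n_samples = 10, n_windows = 1,
                        components_per_window = 3, n_is = 0, overlap = 0.5,
                        snr = 100, baseline_drift = 0, seed = 4)
  tr <- ground_truth(cube)
  rf <- resolve_window(segment_windows(cube, 1)[[1]])
  expect_identical(nrow(rf), 3L)
  asg <- best_assignment(rf$spectrum, tr$spectra)
  expect_identical(sort(asg$assignment), 1:3)   # a true one-to-one matching
  expect_true(all(asg$cosines > 0.95))
})

test_that("resolved features reconstruct noise-free windows within 1%", {
  cube <- simulate_cube(n_samples = 5, n_windows = 1,
                        components_per_window = 2, n_is = 0, overlap = 0.5,
                        snr = Inf, baseline_drift = 0, seed = 8)
  w <- segment_windows(cube, 1)[[1]]
  rf <- resolve_window(w)
  for (s in seq_len(dim(w$tensor)[1])) {
    recon <- matrix(0, length(w$time), length(cube$mz))
    for (j in seq_len(nrow(rf))) {
      prof <- rf$elution_profile[[j]]
      prof <- prof / pracma::trapz(w$time, prof)
      recon <- recon + rf$areas[[j]][s] * outer(prof, rf$spectrum[[j]])
    }
    expect_lt(norm(w$tensor[s, , ] - recon, "F") / norm(w$tensor[s, , ], "F"),
              0.01)
  }
})

test_that("an all-zero window resolves to an empty feature set", {
  w <- list(index = 1L, start = 0L, end = 10L, time = 1:10,
            tensor = array(0, dim = c(2, 10, 5)),
            samples = c("A", "B"), mz = 50:54)
  expect_identical(nrow(resolve_window(w)), 0L)
})

test_that("permuting sample order permutes resolved areas identically", {
  cube <- simulate_cube(n_samples = 6, n_windows = 1,
                        components_per_window = 2, overlap = 0.5, snr = 100,
                        seed = 10)
  perm <- c(4, 1, 6, 2, 5, 3)
  cube2 <- cube
  cube2$intensities <- cube$intensities[perm, , ]
  cube2$samples <- cube$samples[perm]
  a1 <- areas_matrix(resolve_window(segment_windows(cube, 1)[[1]]))
  a2 <- areas_matrix(resolve_window(segment_windows(cube2, 1)[[1]]))
  expect_equal(unname(a1[perm, ]), unname(a2), tolerance = 1e-10)
})

test_that("raising snr never degrades median spectral recovery", {
  med_cos <- vapply(c(5, 25, 100), function(snr) {
    cosines <- vapply(1:3, function(sd) {
      cube <- simulate_cube(n_samples = 6, n_windows = 1,
                            components_per_window = 2, overlap = 0.5,
                            snr = snr, seed = sd)
      tr <- ground_truth(cube)
      rf <- resolve_window(segment_windows(cube, 1)[[1]])
      if (nrow(rf) != 2) return(0)
      min(best_assignment(rf$spectrum, tr$spectra)$cosines)
    }, numeric(1))
    median(cosines)
  }, numeric(1))
  expect_true(all(diff(med_cos) >= -1e-12))
})

test_that("retention indices interpolate linearly between markers", {
  markers <- tibble::tibble(time = c(100, 200, 400), ri = c(1000, 1100, 1200))
  f <- tibble::tibble(component = c("a", "b", "c"), window = 1L,
                      apex_time = c(200, 150, 300), converged = TRUE,
                      elution_profile = list(1, 1, 1),
                      spectrum = list(1, 1, 1), areas = list(1, 1, 1))
  out <- assign_retention_index(f, markers)
  expect_equal(out$retention_index, c(1100, 1050, 1150))
  expect_false(any(out$ri_extrapolated))
  # outside the marker range: extrapolated and flagged
  f$apex_time <- c(50, 200, 500)
  out <- assign_retention_index(f, markers)
  expect_identical(out$ri_extrapolated, c(TRUE, FALSE, TRUE))
  expect_equal(out$retention_index[1], 1000 - 50 * (100 / 100))
  expect_error(assign_retention_index(f, markers[1, ]), "markers")
})

test_that("library matching is gated by retention index and cosine", {
  mzn <- 40
  set.seed(42)
  specs <- lapply(1:3, function(i) {
    s <- numeric(mzn); s[sample(mzn, 6)] <- runif(6); s / sum(s)
  })
  lib <- spectral_library(c("X", "Y", "Z"), c(1100, 1200, 1300), specs)
  f <- tibble::tibble(component = "q", window = 1L, apex_time = 1,
                      converged = TRUE, elution_profile = list(1),
                      spectrum = specs[2], areas = list(1),
                      retention_index = 1195, ri_extrapolated = FALSE)
  hit <- match_library(f, lib, min_score = 0.8, ri_tol = 30)
  expect_identical(hit$putative_id, "Y")
  expect_equal(hit$match_score, 1, tolerance = 1e-12)
  # same spectrum but RI out of tolerance: no identity
  f$retention_index <- 1000
  miss <- match_library(f, lib, min_score = 0.8, ri_tol = 30)
  expect_true(is.na(miss$putative_id))
})

test_that("a noisy spectrum is matched to the right entry among decoys", {
  mzn <- 60
  set.seed(7)
  specs <- lapply(1:21, function(i) {
    s <- numeric(mzn); s[sample(mzn, 8)] <- runif(8, 0.2, 1); s / sum(s)
  })
  lib <- spectral_library(sprintf("M%02d", 1:21), rep(1100, 21), specs)
  noisy <- specs[[13]] + abs(rnorm(mzn, 0, max(specs[[13]]) / 50))
  f <- tibble::tibble(component = "q", window = 1L, apex_time = 1,
                      converged = TRUE, elution_profile = list(1),
                      spectrum = list(noisy / sum(noisy)), areas = list(1),
                      retention_index = 1100, ri_extrapolated = FALSE)
  hit <- match_library(f, lib, min_score = 0.5, ri_tol = 50)
  expect_identical(hit$putative_id, "M13")
  # brute-force: the reported score is the maximum over all entries
  all_scores <- vapply(specs, function(s) cos_sim(f$spectrum[[1]], s),
                       numeric(1))
  expect_equal(hit$match_score, max(all_scores), tolerance = 1e-12)
})

test_that("internal-standard normalization removes sample recovery factors", {
  # hand case: all IS areas 1 leaves features unchanged
  f <- tibble::tibble(
    component = c("F1", "F2", "IS1"), window = 1L, apex_time = c(1, 2, 3),
    converged = TRUE, elution_profile = list(1, 1, 1),
    spectrum = list(1, 1, 1),
    areas = list(c(A = 2, B = 3), c(A = 4, B = 5), c(A = 1, B = 1)),
    retention_index = c(1000, 1010, 1020)
  )
  out <- normalize_by_is(f, "IS1")
  expect_identical(feature_cols(out), c("F1", "F2"))
  expect_equal(unname(feature_matrix(out)), matrix(c(2, 3, 4, 5), 2),
               tolerance = 1e-12)
  # scale invariance: tripling one sample's raw signal changes nothing
  f2 <- f
  f2$areas <- lapply(f$areas, function(a) { a["A"] <- a["A"] * 3; a })
  out2 <- normalize_by_is(f2, "IS1")
  expect_equal(feature_matrix(out2)["A", ], feature_matrix(out)["A", ],
               tolerance = 1e-12)
  # nonpositive IS area flags the sample for exclusion
  f3 <- f
  f3$areas[[3]]["B"] <- 0
  out3 <- normalize_by_is(f3, "IS1")
  expect_identical(attr(out3, "excluded")$sample_id, "B")
  expect_identical(rownames(feature_matrix(out3)), "A")
})

test_that("normalization reduces the CV of null features on simulated cubes", {
  cube <- simulate_cube(n_samples = 12, n_windows = 3,
                        components_per_window = 2, n_is = 3, overlap = 0.2,
                        snr = 200, seed = 5)
  tr <- ground_truth(cube)
  feats <- resolve_cube(cube, n_windows = 3)
  lib <- truth_library(cube)
  feats <- match_library(feats, lib, min_score = 0.9, ri_tol = 50)
  is_names <- tr$components$component[tr$components$is_standard]
  expect_true(all(is_names %in% feats$putative_id))
  tab <- normalize_by_is(feats, is_names)
  A_raw <- areas_matrix(feats)
  analyte_cols <- which(!feats$putative_id %in% is_names)
  cv <- function(x) sd(x) / mean(x)
  cv_raw <- mean(apply(A_raw[, analyte_cols, drop = FALSE], 2, cv))
  cv_norm <- mean(apply(feature_matrix(tab), 2, cv))
  expect_lt(cv_norm, cv_raw)
})

test_that("adjacent-window split components are merged by the cosine rule", {
  sp <- c(0.2, 0.5, 0.3)
  f <- tibble::tibble(
    component = c("W01F1", "W02F1"), window = 1:2, apex_time = c(10, 10.5),
    converged = TRUE, elution_profile = list(1, 1),
    spectrum = list(sp, sp + c(0, 1e-4, 0)),
    areas = list(c(A = 1, B = 2), c(A = 0.5, B = 0.25))
  )
  merged <- merge_split_features(f, dt = 0.5)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$areas[[1]], c(A = 1.5, B = 2.25), tolerance = 1e-12)
})
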