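# Independent oracles used across the suite.  These deliberately re-derive
# quantities by brute force / closed form, never by calling the package's
# own implementation path.

cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# AUC by explicit all-pairs counting (half credit for ties)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by full enumeration of label assignments
# (no ties assumed); U = pairs where a-value exceeds b-value
mw_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  u_obs <- sum(outer(a, b, `>`))
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2L, function(idx) {
    sum(outer(pool[idx], pool[-idx], `>`))
  })
  dev <- abs(us - na * nb / 2)
  p <- mean(dev >= abs(u_obs - na * nb / 2))
  list(U = u_obs, p = p)
}

# first-component NIPALS PLS for a single centered response: closed form
nipals_pls1 <- function(X, y) {
  yc <- y - mean(y)
  w <- crossprod(X, yc)
  w <- w / sqrt(sum(w^2))
  t1 <- X %*% w
  list(w = as.numeric(w), t = as.numeric(t1))
}

# best one-to-one assignment of resolved to true components by spectral
# cosine, brute force over all permutations (k <= 4)
best_assignment <- function(res_spectra, true_spectra) {
  k <- length(res_spectra)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_sum <- -Inf
  for (p in perms(seq_len(k))) {
    s <- sum(vapply(seq_len(k), function(i) {
      cos_sim(res_spectra[[i]], true_spectra[p[i], ])
    }, numeric(1)))
    if (s > best_sum) { best_sum <- s; best <- p }
  }
  cosines <- vapply(seq_len(k), function(i) {
    cos_sim(res_spectra[[i]], true_spectra[best[i], ])
  }, numeric(1))
  list(assignment = best, cosines = cosines)
}

# small hand-built cube for baseline / segmentation tests
make_cube <- function(intensities, time, mz, ri_markers = NULL) {
  ns <- dim(intensities)[1L]
  if (is.null(ri_markers)) {
    ri_markers <- tibble::tibble(time = range(time), ri = c(1000, 2000))
  }
  structure(list(samples = sprintf("S%03d", seq_len(ns)), time = time,
                 mz = mz, intensities = intensities, ri_markers = ri_markers),
            class = "gc_cube")
}
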