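#' Simulate a class-structured metabolite feature table
#'
#' Generates a strictly positive, log-normal feature table with a two-class
#' design and a small planted set of informative features, emulating the
#' structure of a resolved and normalized GC-TOFMS metabolomics matrix
#' (roughly 200 features of which a handful separate the classes).
#'
#' On the log scale every feature is Gaussian with feature-specific location
#' and scale; informative features receive a class-mean shift of
#' `effect_size` pooled standard deviations (a standardized mean difference,
#' Cohen's d), with a random sign per feature so that both elevated and
#' lowered features occur.  `correlation` introduces a shared within-class
#' factor across the informative block.
#'
#' @param n_per_class Integer vector of length 2: samples in class 0 and 1.
#' @param n_features Total number of features.
#' @param n_informative Number of informative (class-separating) features.
#' @param effect_size Standardized mean difference on the log scale
#'   (Cohen's d, unitless, >= 0).
#' @param correlation Within-block correlation (0-1) among informative
#'   features, induced by a shared latent factor.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A feature-table tibble (`sample_id`, `class`, `survival_months`,
#'   feature columns) carrying a `truth` attribute (see [ground_truth()])
#'   with elements `informative_features`, `effect_size`, `signs`,
#'   `class_labels`, `log_location`, `log_scale`.
#' @examples
#' tbl <- simulate_feature_table(c(10, 10), n_features = 30, seed = 1)
#' ground_truth(tbl)$informative_features
#' @export
simulate_feature_table <- function(n_per_class = c(40L, 40L),
                                   n_features = 200L,
                                   n_informative = 10L,
                                   effect_size = 2,
                                   correlation = 0.3,
                                   seed = 1L) {
  if (length(n_per_class) != 2L) abort("`n_per_class` must have length 2")
  n0 <- check_count(n_per_class[1L], "n_per_class[1]")
  n1 <- check_count(n_per_class[2L], "n_per_class[2]")
  p <- check_count(n_features, "n_features")
  ni <- check_count(n_informative, "n_informative", min = 0L)
  if (ni > p) abort("`n_informative` must not exceed `n_features`")
  if (!is.numeric(effect_size) || effect_size < 0) abort("`effect_size` must be >= 0")
  rho <- check_fraction(correlation, "correlation")

  n <- n0 + n1
  y <- c(rep(0L, n0), rep(1L, n1))
  withr::with_seed(seed, {
    mu <- rnorm(p, mean = log(100), sd = 0.8)     # feature-specific abundance
    sig <- runif(p, 0.3, 0.7)                     # log-scale within-class SD
    inf_idx <- if (ni > 0L) sort(sample.int(p, ni)) else integer(0)
    signs <- rep(0L, p)
    if (ni > 0L) signs[inf_idx] <- sample(c(-1L, 1L), ni, replace = TRUE)

    z <- matrix(rnorm(n * p), n, p)
    if (ni > 0L && rho > 0) {
      f <- rnorm(n)                               # shared within-class factor
      z[, inf_idx] <- sqrt(rho) * f + sqrt(1 - rho) * z[, inf_idx]
    }
    shift <- outer(y, signs) * effect_size        # d pooled SDs on log scale
    logx <- sweep(sweep(z + shift, 2L, sig, `*`), 2L, mu, `+`)
    X <- exp(logx)
  })
  colnames(X) <- sprintf("F%03d", seq_len(p))

  meta <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    class = y,
    survival_months = NA_real_
  )
  tbl <- as_feature_table(X, meta)
  attr(tbl, "truth") <- list(
    informative_features = inf_idx,
    effect_size = effect_size,
    signs = signs,
    class_labels = y,
    log_location = mu,
    log_scale = sig
  )
  tbl
}

#' Inject gross outliers and derivatization-style failures into a table
#'
#' Emulates the two kinds of bad samples seen in practice: analytical
#' outliers whose whole profile is scaled by a gross factor, and failed
#' derivatizations where most features collapse to near zero.  Affected
#' sample ids are recorded in the `qc_injected` metadata column.
#'
#' @param table A feature table.
#' @param n_outliers Number of gross-outlier samples to create.
#' @param n_failed Number of failed (near-zero) samples to create.
#' @param seed Integer seed.
#' @param outlier_factor Multiplier applied to every feature of an outlier
#'   sample; the default (8) puts the sample far outside the score-space
#'   interquartile range of its peers.
#' @return The modified feature table; `qc_injected` is `NA`, `"outlier"`
#'   or `"failed"` per sample.
#' @export
inject_failures <- function(table, n_outliers = 0L, n_failed = 0L, seed = 1L,
                            outlier_factor = 8) {
  no <- check_count(n_outliers, "n_outliers", min = 0L)
  nf <- check_count(n_failed, "n_failed", min = 0L)
  n <- nrow(table)
  if (no + nf >= n) abort("`n_outliers` + `n_failed` must be < number of samples")
  if (no + nf == 0L) return(table)

  fc <- feature_cols(table)
  X <- feature_matrix(table)
  qc <- rep(NA_character_, n)
  withr::with_seed(seed, {
    idx <- sample.int(n, no + nf)
    out_idx <- head(idx, no)
    fail_idx <- tail(idx, nf)
    X[out_idx, ] <- X[out_idx, , drop = FALSE] * outlier_factor
    floor_val <- stats::median(X) * 1e-4
    for (i in fail_idx) {
      hit <- sample.int(length(fc), ceiling(0.8 * length(fc)))
      X[i, hit] <- floor_val
    }
  })
  qc[out_idx] <- "outlier"
  qc[fail_idx] <- "failed"

  out <- table
  out[fc] <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  out$qc_injected <- qc
  # keep metadata columns in front of feature columns
  out <- dplyr::relocate(out, dplyr::any_of(META_COLS))
  attr(out, "truth") <- attr(table, "truth", exact = TRUE)
  attr(out, "feature_meta") <- attr(table, "feature_meta", exact = TRUE)
  out
}
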