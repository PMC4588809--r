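#' @importFrom rlang abort warn %||%
#' @importFrom stats sd var median quantile qf pf pnorm rnorm rlnorm runif
#' @importFrom stats prcomp wilcox.test setNames
#' @importFrom utils head tail
NULL

# rolling minimum with edge extension; wl must be odd
roll_min <- function(x, wl) {
  n <- length(x)
  h <- (wl - 1L) / 2L
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  apply(embed(xp, wl), 1L, min)
}

roll_max <- function(x, wl) {
  n <- length(x)
  h <- (wl - 1L) / 2L
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  apply(embed(xp, wl), 1L, max)
}

# centered moving average with edge extension
roll_mean <- function(x, wl) {
  n <- length(x)
  h <- (wl - 1L) / 2L
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  as.numeric(stats::filter(xp, rep(1 / wl, wl), sides = 2L))[(h + 1L):(h + n)]
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# enforce unimodality on a non-negative vector by clipping secondary bumps
# from the apex outward (each step away from the apex cannot increase)
enforce_unimodal <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  a <- which.max(v)
  if (a > 1L) for (i in (a - 1L):1L) v[i] <- min(v[i], v[i + 1L])
  if (a < n) for (i in (a + 1L):n) v[i] <- min(v[i], v[i - 1L])
  v
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}
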