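#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures for a single binary response:
#' `A_orth` components of y-orthogonal structured variation are estimated
#' and removed from X, then a single predictive component is fitted on the
#' filtered matrix (all final models here are of "1 + A_orth + 0" form; with
#' one response there is at most one predictive component).  With
#' `A_orth = 0` the fit reduces exactly to first-component NIPALS PLS.
#'
#' The predictive weight vector `w_star` has unit norm and is oriented so
#' that the class coded 1 has positive mean predictive score.  `R2X` is the
#' fraction of (scaled) X variance captured by the predictive plus
#' orthogonal components; `R2Y` the fraction of centered response variance
#' explained.
#'
#' @param table A scaled feature table (see [scale_features()]) or a numeric
#'   matrix assumed already centered/scaled.
#' @param y Binary response: 0/1 vector, logical, or two-level factor; each
#'   class needs >= 3 samples.
#' @param A_orth Number of orthogonal components (>= 0, < rank of X).
#' @return An `opls_model`: `w_star`, `t_pred`, `p_pred`, `q`, `t_orth`,
#'   `w_orth`, `p_orth`, `A_pred` (always 1), `A_orth`, `R2X`, `R2Y`,
#'   `y_mean`, `scaling`, `features`, `sample_id`.
#' @export
fit_opls <- function(table, y, A_orth = 0L) {
  A_orth <- check_count(A_orth, "A_orth", min = 0L)
  if (is.matrix(table)) {
    X <- table
    scaling <- NULL
    sample_id <- rownames(table) %||% as.character(seq_len(nrow(table)))
  } else {
    scaling <- attr(table, "scaling")
    if (is.null(scaling)) abort("table must be scaled first (see scale_features())")
    X <- feature_matrix(table)
    sample_id <- as.character(table$sample_id)
  }
  y <- as_binary(y)
  if (length(y) != nrow(X)) abort("`y` length must match the number of samples")
  if (length(unique(y)) < 2L) abort("`y` must contain both classes")
  if (min(table(y)) < 3L) abort("each class needs at least 3 samples")
  if (A_orth >= min(nrow(X) - 1L, ncol(X))) abort("`A_orth` must be < rank(X)")

  core <- opls_core(X, y, A_orth)
  structure(c(core, list(scaling = scaling, features = colnames(X),
                         sample_id = sample_id, y = y)),
            class = "opls_model")
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) y <- as.integer(factor(y)) - 1L
  if (!all(y %in% c(0, 1))) abort("`y` must be binary (two classes)")
  as.numeric(y)
}

# X already centered/scaled; y on 0/1 scale
opls_core <- function(X, y, A_orth) {
  n <- nrow(X); p <- ncol(X)
  y_mean <- mean(y)
  yc <- y - y_mean
  ss_x0 <- sum(X^2)
  Xf <- X
  W_o <- P_o <- matrix(0, p, A_orth)
  T_o <- matrix(0, n, A_orth)
  for (i in seq_len(A_orth)) {
    w <- crossprod(Xf, yc)
    w <- w / sqrt(sum(w^2))
    tt <- Xf %*% w
    pp <- crossprod(Xf, tt) / sum(tt^2)
    w_o <- pp - as.numeric(crossprod(w, pp)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-10 * sqrt(sum(pp^2))) {
      # predictive loading already lies along w: nothing orthogonal to
      # remove, so the model degrades gracefully to fewer components
      W_o <- W_o[, seq_len(i - 1L), drop = FALSE]
      P_o <- P_o[, seq_len(i - 1L), drop = FALSE]
      T_o <- T_o[, seq_len(i - 1L), drop = FALSE]
      A_orth <- i - 1L
      break
    }
    w_o <- w_o / nw
    t_o <- Xf %*% w_o
    p_o <- crossprod(Xf, t_o) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_o[, i] <- w_o; P_o[, i] <- p_o; T_o[, i] <- t_o
  }
  w <- crossprod(Xf, yc)
  w <- w / sqrt(sum(w^2))
  t_p <- Xf %*% w
  p_p <- crossprod(Xf, t_p) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)
  # orient so class 1 has positive mean predictive score
  if (mean(t_p[y == 1]) < mean(t_p[y == 0])) {
    w <- -w; t_p <- -t_p; p_p <- -p_p; q <- -q
  }
  E <- Xf - tcrossprod(t_p, p_p)
  r2x <- 1 - sum(E^2) / ss_x0
  r2y <- 1 - sum((yc - t_p * q)^2) / sum(yc^2)
  list(A_pred = 1L, A_orth = A_orth,
       w_star = setNames(as.numeric(w), colnames(X)),
       t_pred = as.numeric(t_p), p_pred = as.numeric(p_p), q = q,
       t_orth = T_o, w_orth = W_o, p_orth = P_o,
       R2X = r2x, R2Y = r2y, y_mean = y_mean,
       ss_pred = sum(tcrossprod(t_p, p_p)^2),
       ss_orth = if (A_orth > 0) sum((T_o %*% t(P_o))^2) else 0,
       ss_resid = sum(E^2), ss_total = ss_x0)
}

#' Predict OPLS scores and responses for new samples
#'
#' Applies the model's stored scaling (when the model was fitted on a
#' table), removes the orthogonal components with the training loadings,
#' and projects onto `w_star`.
#'
#' @param object An `opls_model`.
#' @param newdata A feature table (unscaled, when the model holds a scaling)
#'   or a numeric matrix on the training scale.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `t_pred`, `y_hat`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    X <- newdata[, object$features, drop = FALSE]
    sid <- rownames(newdata) %||% as.character(seq_len(nrow(newdata)))
  } else {
    if (!is.null(object$scaling)) {
      newdata <- apply_scaling(newdata, object$scaling)
    }
    X <- feature_matrix(newdata)[, object$features, drop = FALSE]
    sid <- as.character(newdata$sample_id)
  }
  for (i in seq_len(object$A_orth)) {
    t_o <- X %*% object$w_orth[, i]
    X <- X - tcrossprod(t_o, object$p_orth[, i])
  }
  t_p <- as.numeric(X %*% object$w_star)
  tibble::tibble(sample_id = sid, t_pred = t_p,
                 y_hat = object$y_mean + t_p * object$q)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> A = 1 + %d + 0, R2X = %.3f, R2Y = %.3f (%d features)\n",
              x$A_orth, x$R2X, x$R2Y, length(x$w_star)))
  invisible(x)
}

#' Tidy an OPLS model into a per-feature tibble
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return Tibble with `feature`, `w_star`, `p_pred`.
#' @export
tidy.opls_model <- function(x, ...) {
  tibble::tibble(feature = names(x$w_star), w_star = as.numeric(x$w_star),
                 p_pred = x$p_pred)
}

#' One-row model summary in the conventional "A = 1 + a + 0" form
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return Tibble with `A_pred`, `A_orth`, `R2X`, `R2Y`.
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(A_pred = x$A_pred, A_orth = x$A_orth, R2X = x$R2X, R2Y = x$R2Y)
}
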