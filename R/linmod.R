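#' Weighted least squares fit for one element
#'
#' Solves the precision-weighted regression of one element's activities on
#' the design, minimizing `sum(w_i * (y_i - x_i' beta)^2)`.
#'
#' @param activity_row numeric activity values, one per sample.
#' @param weights_row strictly positive precision weights, one per sample.
#' @param design numeric design matrix (samples x coefficients), full column
#'   rank.
#' @return List with `coefficients`, `stdev_unscaled` (square roots of the
#'   diagonal of `(X'WX)^-1`), `cov_unscaled`, `sigma` (residual SD from the
#'   weighted RSS; `NA` when the residual df is 0) and `df_residual`.
#' @export
wls_fit <- function(activity_row, weights_row, design) {
  X <- as.matrix(design)
  .check_design(X, length(activity_row))
  stopifnot(all(is.finite(activity_row)), all(weights_row > 0))
  .wls_core(activity_row, weights_row, X)
}

.check_design <- function(X, n) {
  if (nrow(X) != n) stop("design error: design rows must match samples")
  if (qr(X)$rank < ncol(X)) stop("design error: design matrix is rank deficient")
  invisible(TRUE)
}

.wls_core <- function(y, w, X) {
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  XtX <- crossprod(Xw)
  cov_unscaled <- chol2inv(chol(XtX))
  beta <- drop(cov_unscaled %*% crossprod(Xw, yw))
  names(beta) <- colnames(X)
  res <- yw - drop(Xw %*% beta)
  df <- length(y) - ncol(X)
  sigma <- if (df > 0) sqrt(sum(res^2) / df) else NA_real_
  list(coefficients = beta,
       stdev_unscaled = sqrt(diag(cov_unscaled)),
       cov_unscaled = cov_unscaled,
       sigma = sigma, df_residual = df)
}

#' Generalized least squares fit under block compound symmetry
#'
#' Same contract as [wls_fit()], but observations are correlated with a
#' common correlation `rho` within blocks (e.g. the two alleles measured in
#' the same transfection).  Observation variances are `1/weights`;
#' `rho = 0` reduces exactly to [wls_fit()].
#'
#' @inheritParams wls_fit
#' @param block factor of block ids, one per sample.
#' @param rho within-block correlation, `|rho| < 1`.
#' @return As [wls_fit()].
#' @export
gls_fit <- function(activity_row, weights_row, design, block, rho) {
  X <- as.matrix(design)
  .check_design(X, length(activity_row))
  stopifnot(abs(rho) < 1, all(weights_row > 0))
  block <- as.factor(block)
  if (length(block) != length(activity_row))
    stop("design error: block must have one entry per sample")
  n <- length(activity_row)
  C <- diag(n)
  same <- outer(block, block, `==`)
  C[same & !diag(n)] <- rho
  isw <- 1 / sqrt(weights_row)
  Sigma <- C * tcrossprod(isw)
  U <- chol(Sigma)  # Sigma = t(U) %*% U
  yt <- backsolve(U, activity_row, transpose = TRUE)
  Xt <- backsolve(U, X, transpose = TRUE)
  colnames(Xt) <- colnames(X)
  .wls_core(yt, rep(1, n), Xt)
}

# Newton solve of trigamma(y) == x, used by the moment-matching prior fit.
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in seq_len(50)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Borrows information across elements by fitting a scaled
#' inverse-chi-square prior to the per-element residual variances and
#' returning the posterior (moderated) variances
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`.  The prior parameters are
#' estimated by the standard moments-of-log-variance method: the first two
#' moments of `log(s2)` are matched to the scaled-F distribution via
#' digamma/trigamma identities.  When the observed variances carry no excess
#' spread beyond chi-square sampling noise the prior is degenerate
#' (`d0 = Inf`) and every posterior variance equals `s0^2`.
#'
#' @param s2 per-element residual variances.
#' @param df per-element residual degrees of freedom (recycled).
#' @return List with `df_prior` (`d0`), `s2_prior` (`s0^2`) and `s2_post`.
#'   Elements with zero residual df (or non-finite `s2`) are excluded from
#'   the prior fit but still receive `s2_post` from the shared prior.
#' @export
squeeze_var <- function(s2, df) {
  m <- length(s2)
  if (m < 2L) stop("insufficient data: need >= 2 elements")
  df <- rep_len(as.numeric(df), m)
  ok <- is.finite(s2) & df >= 1
  if (sum(ok) < 2L)
    stop("insufficient data: need >= 2 elements with residual df >= 1")
  s2f <- pmax(s2[ok], 1e-12)  # guard: log of numerically-zero variances
  dfo <- df[ok]
  if (diff(range(s2f)) == 0) {
    d0 <- Inf
    s02 <- s2f[1L]
  } else {
    z <- log(s2f)
    e <- z - digamma(dfo / 2) + log(dfo / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(dfo / 2))
    if (evar > 0) {
      d0 <- 2 * .trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(emean)
    }
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s02, m)
  } else {
    out <- rep(s02, m)
    out[ok] <- (d0 * s02 + dfo * pmax(s2[ok], 0)) / (d0 + dfo)
    out
  }
  list(df_prior = d0, s2_prior = s02, s2_post = s2_post)
}

#' Moderated t statistics
#'
#' Computes per-element moderated t statistics for one coefficient or for a
#' numeric contrast of coefficients, using the empirical-Bayes posterior
#' variances: `t = beta / (stdev_unscaled * sqrt(s2_post))`, referred to a t
#' distribution on `d0 + d` degrees of freedom (standard normal when
#' `d0 = Inf`).
#'
#' @param fit an [mpralm()] fit, or any list with components `coefficients`,
#'   `stdev_unscaled`, `cov_unscaled`, `s2_post`, `df_residual`, `df_prior`.
#' @param coef column index or name of the coefficient to test (default:
#'   the last coefficient).
#' @param contrast optional numeric contrast vector over coefficients;
#'   overrides `coef`.
#' @return `data.frame` with columns `logFC`, `t`, `df_total`, `p_value`.
#' @export
moderated_t <- function(fit, coef = NULL, contrast = NULL) {
  B <- fit$coefficients
  p <- ncol(B)
  if (!is.null(contrast)) {
    if (length(contrast) != p)
      stop("contrast error: contrast must have length ", p)
    est <- drop(B %*% contrast)
    su <- sqrt(apply(fit$cov_unscaled, 3L, function(V)
      drop(crossprod(contrast, V %*% contrast))))
  } else {
    if (is.null(coef)) coef <- p
    if (is.character(coef)) coef <- match(coef, colnames(B))
    if (is.na(coef) || coef < 1 || coef > p)
      stop("contrast error: unknown coefficient")
    est <- B[, coef]
    su <- fit$stdev_unscaled[, coef]
  }
  tt <- est / (su * sqrt(fit$s2_post))
  df_total <- fit$df_prior + fit$df_residual
  pv <- ifelse(is.finite(df_total),
               2 * stats::pt(-abs(tt), df = df_total),
               2 * stats::pnorm(-abs(tt)))
  data.frame(logFC = est, t = tt, df_total = df_total, p_value = pv,
             row.names = rownames(B), stringsAsFactors = FALSE)
}

#' Consensus within-block correlation
#'
#' Estimates a single correlation, shared across elements, between
#' observations in the same block (e.g. the two alleles assayed in one
#' sample).  Per element, the precision-weighted (whitened) residuals of the
#' design fit are formed and their within-block correlation estimated as the
#' mean product over within-block pairs relative to the mean squared
#' residual.  Per-element estimates are combined on the Fisher z scale by a
#' symmetric 15%-trimmed mean and transformed back.
#'
#' @param activity an [ElementActivityMatrix] or a numeric matrix of
#'   activities (elements x samples).
#' @param weights positive weight matrix of the same shape.
#' @param design design matrix (samples x coefficients).
#' @param block factor of block ids; every block must have >= 2 samples.
#' @return The consensus correlation, a number in (-1, 1).
#' @export
estimate_consensus_correlation <- function(activity, weights, design, block) {
  Y <- if (inherits(activity, "ElementActivityMatrix")) activity$activity
       else as.matrix(activity)
  W <- as.matrix(weights)
  X <- as.matrix(design)
  if (is.null(block)) stop("design error: 'block' is required")
  block <- as.factor(block)
  if (any(table(block) < 2))
    stop("design error: every block needs >= 2 samples")
  .check_design(X, ncol(Y))
  pairs <- which(outer(block, block, `==`) &
                 upper.tri(matrix(0, ncol(Y), ncol(Y))), arr.ind = TRUE)
  rho_e <- vapply(seq_len(nrow(Y)), function(e) {
    w <- W[e, ]
    fit <- .wls_core(Y[e, ], w, X)
    r <- sqrt(w) * (Y[e, ] - drop(X %*% fit$coefficients))
    ms <- mean(r^2)
    if (ms <= 0) return(NA_real_)
    mean(r[pairs[, 1L]] * r[pairs[, 2L]]) / ms
  }, numeric(1))
  rho_e <- rho_e[is.finite(rho_e)]
  rho_e <- pmin(pmax(rho_e, -0.99), 0.99)
  tanh(mean(atanh(rho_e), trim = 0.15))
}
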