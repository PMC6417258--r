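#' Copy-number--variance relationship of activity measures
#'
#' Per element, the across-sample standard deviation of the library-size
#' corrected log2 activity measures, paired with the across-sample mean log2
#' aggregated DNA abundance.  MPRA activity measures are more variable for
#' elements present at low copy number, the same shape as the mean-variance
#' trend of RNA-seq log counts, and this profile is the raw material for the
#' precision-weight model.
#'
#' @param activity an [ElementActivityMatrix] with at least 2 samples.
#' @param counts optional [BarcodeCountSet]; unused (abundances are carried
#'   on `activity`), accepted for call-site symmetry.
#' @return `data.frame` with columns `element_id`, `mean_log2_dna`, `sd`.
#' @export
empirical_sd_profile <- function(activity, counts = NULL) {
  stopifnot(inherits(activity, "ElementActivityMatrix"))
  if (ncol(activity$activity) < 2L)
    stop("degenerate input: need at least 2 samples to compute SDs")
  data.frame(element_id = activity$element_ids,
             mean_log2_dna = activity$mean_log2_dna,
             sd = apply(activity$activity, 1L, stats::sd),
             stringsAsFactors = FALSE)
}

#' Fit the precision-weight model
#'
#' Estimates how the residual variability of log2 activity depends on
#' element DNA abundance and converts the trend into observation-level
#' precision weights.  Per element, the residual SD of the activities after
#' removing the design's fitted means is computed; the square root of these
#' SDs is regressed on mean log2 DNA abundance with a lowess smoother; the
#' smoothed value, evaluated at each observation's own sample-specific log2
#' DNA abundance, is raised to the 4th power (undoing the fourth-root scale)
#' and inverted to give that observation's weight.
#'
#' @param activity an [ElementActivityMatrix] with at least 10 elements.
#' @param design numeric design matrix (samples x coefficients).
#' @param span lowess smoother span in (0, 1]; default 0.3.
#' @return A `WeightModel`: list with `curve_x`, `curve_y` (the fitted
#'   sqrt-SD trend), `smoother_span` and `weights` (elements x samples,
#'   strictly positive and finite).
#' @export
fit_weight_curve <- function(activity, design, span = 0.3) {
  stopifnot(inherits(activity, "ElementActivityMatrix"))
  Y <- activity$activity
  if (nrow(Y) < 10L)
    stop("insufficient data: need >= 10 elements to fit the variance trend")
  X <- as.matrix(design)
  stopifnot(nrow(X) == ncol(Y), span > 0, span <= 1)
  df <- nrow(X) - qr(X)$rank
  if (df < 1L) stop("design error: no residual degrees of freedom")
  # unweighted per-element residual SD about the design fit
  Q <- diag(nrow(X)) - X %*% solve(crossprod(X), t(X))
  R <- Y %*% Q
  sdev <- sqrt(rowSums(R^2) / df)
  x <- activity$mean_log2_dna
  y <- sqrt(sdev)
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok))
    warning(sum(!ok), " elements with non-finite SD excluded from the trend")
  # average y within duplicate x before smoothing
  xs <- x[ok]; ys <- y[ok]
  if (anyDuplicated(xs)) {
    ys <- as.numeric(tapply(ys, xs, mean))
    xs <- sort(unique(xs))
  }
  fit <- stats::lowess(xs, ys, f = span)
  # constant extrapolation beyond observed range; floor keeps weights finite
  pred <- function(x0) {
    yy <- stats::approx(fit$x, fit$y, xout = x0, rule = 2, ties = "ordered")$y
    pmax(yy, 1e-3)
  }
  sqrt_sd_obs <- matrix(pred(as.numeric(activity$log2_dna)),
                        nrow = nrow(Y), ncol = ncol(Y),
                        dimnames = dimnames(Y))
  w <- 1 / sqrt_sd_obs^4
  structure(list(curve_x = fit$x, curve_y = pmax(fit$y, 1e-3),
                 smoother_span = span, weights = w, predict = pred),
            class = "WeightModel")
}

#' @export
print.WeightModel <- function(x, ...) {
  cat("WeightModel: lowess sqrt-SD trend on", length(x$curve_x),
      "abundance points, span", x$smoother_span, "\n")
  cat("  weight range:", format(range(x$weights), digits = 4), "\n")
  invisible(x)
}

#' Plot the fitted copy-number--variance trend
#'
#' @param x a `WeightModel`.
#' @param activity optional [ElementActivityMatrix] to overlay the empirical
#'   sqrt-SD scatter the curve was fit to.
#' @param ... passed to [graphics::plot()].
#' @export
plot.WeightModel <- function(x, activity = NULL, ...) {
  graphics::plot(x$curve_x, x$curve_y, type = "l", col = "red", lwd = 2,
                 xlab = "mean log2 DNA abundance",
                 ylab = "sqrt( SD of log2 activity )", ...)
  if (!is.null(activity)) {
    prof <- empirical_sd_profile(activity)
    graphics::points(prof$mean_log2_dna, sqrt(prof$sd), pch = 16,
                     cex = 0.3, col = "grey40")
    graphics::lines(x$curve_x, x$curve_y, col = "red", lwd = 2)
  }
  invisible(x)
}
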