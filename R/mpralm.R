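#' Precision-weighted moderated linear models for MPRA differential activity
#'
#' The main fitting function.  Runs the full analysis pipeline on
#' barcode-level counts: total-count normalization, barcode summarization
#' into element-level log2 activity measures, low-DNA / constant-ratio
#' filtering, estimation of the copy-number--variance trend and derived
#' observation-level precision weights, per-element (generalized) weighted
#' least squares, empirical-Bayes variance moderation and moderated t
#' statistics for every coefficient.  For paired designs (e.g. two alleles
#' measured in the same transfection) a consensus within-block correlation
#' is estimated and used in a generalized least squares fit.
#'
#' @param counts a [BarcodeCountSet].
#' @param design either a one-sided formula evaluated on the sample sheet
#'   (default `~ condition`) or a numeric design matrix
#'   (samples x coefficients).
#' @param estimator barcode summarization: `"aggregate"` (default) or
#'   `"average"`.
#' @param span lowess span for the variance trend (default 0.3).
#' @param block `NULL` for independent samples, otherwise the name of a
#'   sample-sheet column (or a vector of block ids) defining paired samples.
#' @param min_dna element filter: minimum aggregated DNA count required in
#'   every sample (default 10); set to 0 to disable.
#' @param common_lib_size passed to [total_count_normalize()].
#' @return An object of class `mpralm_fit` with per-element `coefficients`,
#'   `stdev_unscaled`, `sigma`, `df_residual`, the prior `df_prior` (d0) and
#'   `s2_prior` (s0^2), posterior variances `s2_post`, moderated `t` and
#'   `p_value` matrices (one column per coefficient), the `weight_model`,
#'   the filtered `activity`, the `design`, and `consensus_correlation`
#'   (`NA` for unpaired fits).  See [top_elements()] for ranked results.
#' @examples
#' sim <- generate_mpra(simulation_spec(n_elements = 60, seed = 7))
#' fit <- mpralm(sim$counts, ~ condition)
#' head(top_elements(fit))
#' @export
mpralm <- function(counts, design = ~ condition,
                   estimator = c("aggregate", "average"),
                   span = 0.3, block = NULL, min_dna = 10,
                   common_lib_size = "mean") {
  stopifnot(inherits(counts, "BarcodeCountSet"))
  estimator <- match.arg(estimator)
  counts <- total_count_normalize(counts, common_lib_size)
  activity <- summarize_dataset(counts, estimator)
  activity <- filter_elements(activity, counts, min_dna = min_dna)
  report <- attr(activity, "filter_report")
  if (length(activity$element_ids) == 0L)
    stop("degenerate input: no elements left after filtering")

  X <- .build_design(design, counts$samples)
  blk <- .resolve_block(block, counts$samples)

  wm <- fit_weight_curve(activity, X, span = span)
  Y <- activity$activity
  W <- wm$weights
  E <- nrow(Y)
  p <- ncol(X)

  rho <- NA_real_
  if (!is.null(blk))
    rho <- estimate_consensus_correlation(activity, W, X, blk)

  coefficients <- matrix(NA_real_, E, p, dimnames = list(activity$element_ids,
                                                         colnames(X)))
  stdev_unscaled <- coefficients
  cov_unscaled <- array(NA_real_, c(p, p, E))
  sigma <- numeric(E)
  df_residual <- numeric(E)
  for (e in seq_len(E)) {
    fit <- if (is.null(blk)) .wls_core(Y[e, ], W[e, ], X)
           else gls_fit(Y[e, ], W[e, ], X, blk, rho)
    coefficients[e, ] <- fit$coefficients
    stdev_unscaled[e, ] <- fit$stdev_unscaled
    cov_unscaled[, , e] <- fit$cov_unscaled
    sigma[e] <- fit$sigma
    df_residual[e] <- fit$df_residual
  }

  sq <- squeeze_var(sigma^2, df_residual)
  out <- list(coefficients = coefficients,
              stdev_unscaled = stdev_unscaled,
              cov_unscaled = cov_unscaled,
              sigma = sigma, df_residual = df_residual,
              df_prior = sq$df_prior, s2_prior = sq$s2_prior,
              s2_post = sq$s2_post,
              consensus_correlation = rho,
              weight_model = wm, activity = activity,
              design = X, block = blk, estimator = estimator,
              filter_report = report)
  tt <- lapply(seq_len(p), function(j) moderated_t(out, coef = j))
  out$t <- do.call(cbind, lapply(tt, `[[`, "t"))
  out$p_value <- do.call(cbind, lapply(tt, `[[`, "p_value"))
  dimnames(out$t) <- dimnames(out$p_value) <- dimnames(coefficients)
  class(out) <- "mpralm_fit"
  out
}

.build_design <- function(design, samples) {
  if (inherits(design, "formula")) {
    X <- stats::model.matrix(design, data = samples)
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  .check_design(X, nrow(samples))
  X
}

.resolve_block <- function(block, samples) {
  if (is.null(block)) return(NULL)
  if (is.character(block) && length(block) == 1L) {
    if (!block %in% names(samples))
      stop("design error: no sample-sheet column named '", block, "'")
    block <- samples[[block]]
  }
  blk <- as.factor(block)
  if (length(blk) != nrow(samples))
    stop("design error: block must have one entry per sample")
  blk
}

#' Ranked differential activity results
#'
#' @param fit an [mpralm()] fit.
#' @param coef coefficient (index or name) to rank by; defaults to the last
#'   design column (the group difference in a two-group model).
#' @param number maximum number of elements to return.
#' @param sort_by `"p"` (default) or `"none"` to keep element order.
#' @return `data.frame` with `element_id`, `logFC` (log2), `t`, `df_total`,
#'   `p_value` and Benjamini-Hochberg `adj_p_value`.
#' @export
top_elements <- function(fit, coef = NULL, number = Inf, sort_by = c("p", "none")) {
  stopifnot(inherits(fit, "mpralm_fit"))
  sort_by <- match.arg(sort_by)
  tab <- moderated_t(fit, coef = coef)
  tab <- data.frame(element_id = rownames(fit$coefficients), tab,
                    stringsAsFactors = FALSE)
  tab$adj_p_value <- stats::p.adjust(tab$p_value, method = "BH")
  if (sort_by == "p") tab <- tab[order(tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, number)
}

#' @export
print.mpralm_fit <- function(x, ...) {
  cat("mpralm fit:", nrow(x$coefficients), "elements,",
      nrow(x$design), "samples,", ncol(x$design), "coefficients (",
      x$estimator, "estimator )\n")
  cat("  prior df d0 =", format(x$df_prior, digits = 4),
      " prior variance s0^2 =", format(x$s2_prior, digits = 4), "\n")
  if (!is.na(x$consensus_correlation))
    cat("  consensus within-block correlation =",
        format(x$consensus_correlation, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.mpralm_fit <- function(object, coef = NULL, alpha = 0.05, ...) {
  tab <- top_elements(object, coef = coef, number = Inf)
  nsig <- sum(tab$adj_p_value <= alpha)
  print(object)
  cat("  elements at BH FDR", alpha, ":", nsig, "\n")
  cat("  dropped in filtering:", nrow(object$filter_report), "\n")
  invisible(tab)
}

#' @export
coef.mpralm_fit <- function(object, ...) object$coefficients

#' @export
fitted.mpralm_fit <- function(object, ...) {
  tcrossprod(object$coefficients, object$design)
}

#' @export
residuals.mpralm_fit <- function(object, ...) {
  object$activity$activity - fitted(object)
}

#' Diagnostic plot of the fitted variance trend
#'
#' @param x an [mpralm()] fit.
#' @param ... passed on to [plot.WeightModel()].
#' @export
plot.mpralm_fit <- function(x, ...) {
  plot(x$weight_model, activity = x$activity,
       main = "copy-number - variance trend", ...)
}
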