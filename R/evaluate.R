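#' Empirical type I error rates
#'
#' Given p values from data known to be fully null, the empirical type I
#' error at level `alpha` is the fraction of tests rejected at `alpha`.
#'
#' @param p_values p values from null comparisons.
#' @param alphas nominal levels.
#' @return `data.frame` with `alpha`, `n_rejected`, `m` and `rate`.
#' @export
empirical_type1 <- function(p_values, alphas = 0.05) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("degenerate input: no p values")
  m <- length(p_values)
  n_rej <- vapply(alphas, function(a) sum(p_values <= a), numeric(1))
  data.frame(alpha = alphas, n_rejected = n_rej, m = m, rate = n_rej / m)
}

#' Estimate the proportion of true null hypotheses
#'
#' Local-fdr based estimate of pi0, the fraction of tested hypotheses that
#' are truly null: the density of p values near 1 relative to the uniform
#' density, via `limma::propTrueNull(method = "lfdr")`, clipped to (0, 1].
#'
#' @param p_values at least 100 p values.
#' @return pi0 estimate in (0, 1].
#' @export
prop_true_null <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100L)
    stop("insufficient data: need >= 100 p values for pi0 estimation")
  pi0 <- limma::propTrueNull(p_values, method = "lfdr")
  min(max(pi0, 1e-8), 1)
}

#' Estimated false discovery rate
#'
#' `FDR = (pi0 * m * type1_rate) / n_rejected`, clipped to `[0, 1]`: the
#' estimated number of false positives (true type I error rate applied to
#' the estimated number of true nulls) over the number of rejections.
#'
#' @param pi0 proportion of true nulls.
#' @param m total number of tests.
#' @param type1_rate estimated true type I error rate at the chosen nominal
#'   level.
#' @param n_rejected number of rejections at that level.
#' @return Estimated FDR in `[0, 1]`; `NA` when `n_rejected` is 0.
#' @export
estimate_fdr <- function(pi0, m, type1_rate, n_rejected) {
  stopifnot(pi0 >= 0, pi0 <= 1, m > 0, type1_rate >= 0)
  if (n_rejected == 0) return(NA_real_)
  min(max(pi0 * m * type1_rate / n_rejected, 0), 1)
}

#' Rejections as a function of observed type I error
#'
#' For every nominal level, pairs the empirical type I error measured on
#' null p values with the number of rejections among observed p values.
#' Plotting rejections against the observed error rate compares methods at
#' matched, rather than nominal, error levels.
#'
#' @param p_null p values from null data.
#' @param p_obs p values from the observed data.
#' @param alphas nominal levels; default log-spaced from 1e-6 to 0.1.
#' @return `data.frame` with `alpha`, `observed_type1`, `n_rejections`.
#' @export
rejections_vs_error <- function(p_null, p_obs,
                                alphas = 10^seq(-6, -1, length.out = 25)) {
  stopifnot(length(p_null) > 0, length(p_obs) > 0)
  t1 <- empirical_type1(p_null, alphas)
  nrj <- vapply(alphas, function(a) sum(p_obs <= a, na.rm = TRUE), numeric(1))
  data.frame(alpha = alphas, observed_type1 = t1$rate, n_rejections = nrj)
}

#' t-test baseline on aggregate activity measures
#'
#' Classical two-sided t-test per element on the element-level activity
#' measures, the common ad-hoc analysis in the MPRA literature.
#'
#' @param activity an [ElementActivityMatrix].
#' @param group factor with two levels, one per sample (e.g.
#'   `samples$condition`).
#' @param paired paired t-test: sample i of group 1 is paired with sample i
#'   of group 2.
#' @return Named vector of p values (`NA` where the test is undefined, e.g.
#'   zero within-group variance).
#' @export
ttest_baseline <- function(activity, group, paired = FALSE) {
  Y <- if (inherits(activity, "ElementActivityMatrix")) activity$activity
       else as.matrix(activity)
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L, length(group) == ncol(Y))
  i1 <- which(group == levels(group)[1])
  i2 <- which(group == levels(group)[2])
  if (paired && length(i1) != length(i2))
    stop("design error: paired test needs equal group sizes")
  min_n <- if (paired) 2L else 2L
  if (length(i1) < min_n || length(i2) < min_n)
    stop("degenerate input: need >= 2 samples (pairs) per group")
  apply(Y, 1L, function(y) {
    tryCatch(stats::t.test(y[i1], y[i2], paired = paired)$p.value,
             error = function(e) NA_real_)
  })
}

#' Fisher's exact test baseline on pooled counts
#'
#' Per element, RNA and DNA counts are summed over samples within each of
#' two groups to form a 2x2 table (RNA/DNA x group), tested with the exact
#' conditional test.  Pooling ignores between-sample variation, which makes
#' the test badly anticonservative on overdispersed data.
#'
#' @param counts a [BarcodeCountSet] with a two-level `condition`.
#' @return Named vector of p values per element (1, with a warning, for
#'   all-zero tables).
#' @export
fisher_baseline <- function(counts) {
  stopifnot(inherits(counts, "BarcodeCountSet"))
  cond <- counts$samples$condition
  if (nlevels(cond) != 2L)
    stop("design error: exact-test baseline needs exactly two groups")
  i1 <- which(cond == levels(cond)[1])
  i2 <- which(cond == levels(cond)[2])
  ragg <- rowsum(counts$rna, counts$element, reorder = FALSE)
  dagg <- rowsum(counts$dna, counts$element, reorder = FALSE)
  r1 <- rowSums(ragg[, i1, drop = FALSE]); r2 <- rowSums(ragg[, i2, drop = FALSE])
  d1 <- rowSums(dagg[, i1, drop = FALSE]); d2 <- rowSums(dagg[, i2, drop = FALSE])
  pv <- vapply(seq_along(r1), function(e) {
    tab <- matrix(c(r1[e], d1[e], r2[e], d2[e]), 2L)
    if (all(tab == 0)) return(NA_real_)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  if (anyNA(pv)) {
    warning(sum(is.na(pv)), " all-zero tables; p set to 1")
    pv[is.na(pv)] <- 1
  }
  names(pv) <- rownames(ragg)
  pv
}
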