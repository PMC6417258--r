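#' Parameters of the count model for estimator theory
#'
#' The parametric assumptions behind the Taylor-series bias and variance
#' approximations: per-barcode RNA counts have mean `mu_r = N_r * p_r` and
#' variance `k_r * mu_r`; DNA counts have mean `mu_d = N_d * p_d` and
#' variance `k_d * mu_d` (negative binomial counts have `k = 1 + phi * mu`).
#' The true activity is `a = log(p_r / p_d)` on the natural-log scale.
#'
#' @param n_r,n_d RNA and DNA library sizes.
#' @param p_d DNA read fraction of the element.
#' @param p_r RNA read fraction.
#' @param a_log2 alternative to `p_r`: the true activity in log2 units,
#'   from which `p_r = p_d * 2^a_log2`.
#' @param k_r,k_d variance inflation constants (`>= 1` for overdispersed
#'   counts).
#' @param b number of barcodes `B`.
#' @param l common library size after total count normalization; defaults to
#'   the mean of `n_r` and `n_d`.
#' @param cov_rd covariance of a barcode's RNA and DNA counts (default 0).
#' @return An `nb_theory_params` list with derived `mu_r`, `mu_d`, `a`.
#' @export
nb_theory_params <- function(n_r, n_d, p_d, p_r = NULL, a_log2 = NULL,
                             k_r = 1, k_d = 1, b = 10,
                             l = mean(c(n_r, n_d)), cov_rd = 0) {
  if (is.null(p_r)) {
    if (is.null(a_log2)) stop("give either p_r or a_log2")
    p_r <- p_d * 2^a_log2
  }
  stopifnot(n_r > 0, n_d > 0, p_r > 0, p_d > 0, k_r >= 1, k_d >= 1,
            b >= 1, l > 0)
  structure(list(n_r = n_r, n_d = n_d, l = l, p_r = p_r, p_d = p_d,
                 k_r = k_r, k_d = k_d, b = b, cov_rd = cov_rd,
                 mu_r = n_r * p_r, mu_d = n_d * p_d,
                 a = log(p_r / p_d)),
            class = "nb_theory_params")
}

#' Approximate bias of the average estimator
#'
#' Second-order Taylor approximation of the bias of the average (mean of
#' per-barcode log-ratios) estimator, on the natural-log scale.  The full
#' form is the complete second-order approximation of `E[estimator] - a`,
#' i.e. the `+1`-offset shift `log((mu_r L/N_r + 1)/(mu_d L/N_d + 1)) - a`
#' plus the curvature terms
#' `(L/N_d)^2 k_d mu_d / (2 (mu_d L/N_d + 1)^2) -
#'  (L/N_r)^2 k_r mu_r / (2 (mu_r L/N_r + 1)^2)`.
#' The large-count simplification (offsets negligible) is
#' `(k_d/mu_d - k_r/mu_r) / 2`.
#'
#' @param params an [nb_theory_params()].
#' @param simplified return the large-count form.
#' @return Bias on the natural-log scale (divide by `log(2)` for log2).
#' @export
bias_average <- function(params, simplified = FALSE) {
  p <- params
  if (simplified) return((p$k_d / p$mu_d - p$k_r / p$mu_r) / 2)
  cr <- p$l / p$n_r; cd <- p$l / p$n_d
  log((p$mu_r * cr + 1) / (p$mu_d * cd + 1)) - p$a +
    cd^2 * p$k_d * p$mu_d / (2 * (p$mu_d * cd + 1)^2) -
    cr^2 * p$k_r * p$mu_r / (2 * (p$mu_r * cr + 1)^2)
}

#' Approximate bias of the aggregate estimator
#'
#' As [bias_average()], for the estimator that sums counts over the `B`
#' barcodes first.  Aggregation divides the large-count bias by `B`, which
#' is why the aggregate estimator is preferred for absolute activity
#' estimation.
#'
#' @inheritParams bias_average
#' @return Bias on the natural-log scale.
#' @export
bias_aggregate <- function(params, simplified = FALSE) {
  p <- params
  if (simplified) return(bias_average(p, simplified = TRUE) / p$b)
  cr <- p$l / p$n_r; cd <- p$l / p$n_d
  B <- p$b
  log((B * p$mu_r * cr + 1) / (B * p$mu_d * cd + 1)) - p$a +
    cd^2 * B * p$k_d * p$mu_d / (2 * (B * p$mu_d * cd + 1)^2) -
    cr^2 * B * p$k_r * p$mu_r / (2 * (B * p$mu_r * cr + 1)^2)
}

#' Approximate variance of the average estimator
#'
#' Taylor variance of the average estimator assuming barcode-specific
#' log-ratios are uncorrelated, including the RNA-DNA covariance cross-term.
#'
#' @inheritParams bias_average
#' @param log2_scale divide by `log(2)^2` to express the variance of the
#'   log2 activity.
#' @return Variance (natural-log scale unless `log2_scale`).
#' @export
var_average <- function(params, log2_scale = FALSE) {
  p <- params
  cr <- p$l / p$n_r; cd <- p$l / p$n_d
  v <- (cr^2 * p$k_r * p$mu_r / (p$mu_r * cr + 1)^2 +
        cd^2 * p$k_d * p$mu_d / (p$mu_d * cd + 1)^2 -
        2 * cr * cd * p$cov_rd / ((p$mu_r * cr + 1) * (p$mu_d * cd + 1))) / p$b
  if (log2_scale) v / log(2)^2 else v
}

#' Approximate variance of the aggregate estimator
#'
#' @inheritParams var_average
#' @return Variance (natural-log scale unless `log2_scale`).
#' @export
var_aggregate <- function(params, log2_scale = FALSE) {
  p <- params
  cr <- p$l / p$n_r; cd <- p$l / p$n_d
  B <- p$b
  v <- cr^2 * B * p$k_r * p$mu_r / (B * p$mu_r * cr + 1)^2 +
       cd^2 * B * p$k_d * p$mu_d / (B * p$mu_d * cd + 1)^2 -
       2 * cr * cd * B * p$cov_rd /
         ((B * p$mu_r * cr + 1) * (B * p$mu_d * cd + 1))
  if (log2_scale) v / log(2)^2 else v
}

# per-group theory params for the power engine; k = 1 + phi * mu is
# evaluated at the per-barcode means.
.power_params <- function(a_log2, dna_lib_size, rna_lib_size, p_d, barcodes,
                          phi_dna, phi_rna) {
  mu_d_bc <- dna_lib_size * p_d / barcodes
  p_r <- p_d * 2^a_log2
  mu_r_bc <- rna_lib_size * p_r / barcodes
  nb_theory_params(n_r = rna_lib_size, n_d = dna_lib_size,
                   p_d = p_d / barcodes, p_r = p_r / barcodes,
                   k_r = 1 + phi_rna * mu_r_bc, k_d = 1 + phi_dna * mu_d_bc,
                   b = barcodes)
}

#' Power of a two-group MPRA comparison
#'
#' Theory-based power calculation.  The per-replicate variance of the
#' aggregate activity estimator is computed from the Taylor approximation
#' for each group (at the baseline activity and at baseline + effect), the
#' standard error of the group difference is `sqrt(v1/n + v2/n)`, and
#' two-sided power is evaluated under the normal approximation at the
#' Bonferroni-adjusted level `alpha / n_tests`:
#' `power = pnorm(-z + |delta|/SE) + pnorm(-z - |delta|/SE)`.
#'
#' @param n_per_group replicates per group (`>= 2`).
#' @param effect_size true log2 fold change `delta`.
#' @param dna_lib_size,rna_lib_size library sizes per sample.
#' @param p_d DNA read fraction of the element; defaults to
#'   `1 / n_elements`.
#' @param n_elements number of elements (used only for the default `p_d`).
#' @param barcodes barcodes per element (default 10).
#' @param phi_dna,phi_rna NB overdispersions (`k = 1 + phi * mu`); the
#'   default 0.25 corresponds to a barcode-level coefficient of variation of
#'   about 50% across replicates, typical of MPRA libraries.
#' @param baseline_activity true log2 activity of the reference group
#'   (default 0.8, typical of real libraries).
#' @param alpha nominal type I error rate (default 0.05).
#' @param n_tests Bonferroni divisor (default 5000).
#' @return Power in `[0, 1]`.
#' @export
power_two_group <- function(n_per_group, effect_size,
                            dna_lib_size, rna_lib_size = dna_lib_size,
                            p_d = NULL, n_elements = 5000, barcodes = 10,
                            phi_dna = 0.25, phi_rna = 0.25,
                            baseline_activity = 0.8,
                            alpha = 0.05, n_tests = 5000) {
  stopifnot(n_per_group >= 2)
  if (is.null(p_d)) p_d <- 1 / n_elements
  alpha_b <- alpha / n_tests
  stopifnot(alpha_b > 0, alpha_b < 1)
  par1 <- .power_params(baseline_activity, dna_lib_size, rna_lib_size, p_d,
                        barcodes, phi_dna, phi_rna)
  par2 <- .power_params(baseline_activity + effect_size, dna_lib_size,
                        rna_lib_size, p_d, barcodes, phi_dna, phi_rna)
  v1 <- var_aggregate(par1, log2_scale = TRUE)
  v2 <- var_aggregate(par2, log2_scale = TRUE)
  se <- sqrt(v1 / n_per_group + v2 / n_per_group)
  z <- stats::qnorm(1 - alpha_b / 2)
  ncp <- abs(effect_size) / se
  stats::pnorm(-z + ncp) + stats::pnorm(-z - ncp)
}

#' Power table over library size, sample size and effect size
#'
#' Evaluates [power_two_group()] over a grid, for choosing sequencing depth
#' and replicate numbers.  The `meets_recommendation` flag marks designs
#' with at least 4 samples per condition.
#'
#' @param n_per_group,effect_size,dna_lib_size vectors defining the grid.
#' @param ... further arguments passed to [power_two_group()].
#' @return `data.frame` with one row per grid cell: `dna_lib_size`,
#'   `n_per_group`, `effect_size`, `power`, `meets_recommendation`.
#' @export
power_table <- function(n_per_group = c(2, 4, 6, 8, 10),
                        effect_size = c(0.5, 1, 1.5),
                        dna_lib_size = c(1e6, 5e6, 2e7), ...) {
  grid <- expand.grid(dna_lib_size = dna_lib_size,
                      n_per_group = n_per_group,
                      effect_size = effect_size,
                      KEEP.OUT.ATTRS = FALSE)
  grid$power <- mapply(function(L, n, d)
    power_two_group(n_per_group = n, effect_size = d, dna_lib_size = L, ...),
    grid$dna_lib_size, grid$n_per_group, grid$effect_size)
  grid$meets_recommendation <- grid$n_per_group >= 4
  grid
}
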