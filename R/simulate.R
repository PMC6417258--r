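#' Specification of a synthetic MPRA experiment
#'
#' Collects the parameters of the negative-binomial count model used by
#' [generate_mpra()].  Per-barcode DNA counts are NB with mean
#' `mu_d = N_d * p_d / B` and variance `(1 + phi_d * mu_d) * mu_d`; RNA
#' counts are NB with mean `mu_d * 2^a * (N_r / N_d)`, so that `a` is the
#' element's true log2 activity.  Element read fractions `p_d` are
#' log-normal, which reproduces the wide copy-number spread of real plasmid
#' libraries and hence the decreasing copy-number--variance trend.
#'
#' Defaults describe a typical small differential-analysis study: 1000
#' elements at 10 barcodes each, 4 samples per group, overdispersion
#' `phi = 2`, element-level DNA depth of a few hundred reads, and true
#' activities centered at 0.8 log2 units.
#'
#' @param n_elements number of elements.
#' @param barcodes_per_element barcodes per element `B`.
#' @param samples_per_group integer vector `c(n1, n2)`.
#' @param dna_lib_size,rna_lib_size per-sample library sizes `N_d`, `N_r`.
#' @param copy_number_sdlog log-normal sdlog of the element DNA read
#'   fractions `p_d`; `meanlog` is set so that fractions average
#'   `1/n_elements`.
#' @param activity_mean,activity_sd normal distribution of true log2
#'   activities `a`.
#' @param effect_fraction fraction of elements given a true group
#'   difference.
#' @param effect_size true log2 fold change added to group 2 for affected
#'   elements.
#' @param phi_dna,phi_rna NB overdispersions (variance `(1+phi*mu)*mu`);
#'   0 gives Poisson counts.
#' @param activity_noise_sd SD (log2) of per-observation biological noise
#'   added to the activity before counts are drawn.
#' @param within_block_correlation for paired designs: fraction of the
#'   activity-noise variance shared by the two samples of a block, i.e. the
#'   within-block correlation of the biological noise.
#' @param paired if `TRUE`, samples are organized in blocks pairing sample i
#'   of group 1 with sample i of group 2 (requires `n1 == n2`).
#' @param seed integer seed; the generator is fully reproducible.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_elements = 1000,
                            barcodes_per_element = 10,
                            samples_per_group = c(4, 4),
                            dna_lib_size = 2e5,
                            rna_lib_size = 2e5,
                            copy_number_sdlog = 1,
                            activity_mean = 0.8,
                            activity_sd = 0.5,
                            effect_fraction = 0,
                            effect_size = 0,
                            phi_dna = 2,
                            phi_rna = 2,
                            activity_noise_sd = 0,
                            within_block_correlation = 0,
                            paired = FALSE,
                            seed = 1) {
  spec <- list(n_elements = n_elements,
               barcodes_per_element = barcodes_per_element,
               samples_per_group = samples_per_group,
               dna_lib_size = dna_lib_size, rna_lib_size = rna_lib_size,
               copy_number_sdlog = copy_number_sdlog,
               activity_mean = activity_mean, activity_sd = activity_sd,
               effect_fraction = effect_fraction, effect_size = effect_size,
               phi_dna = phi_dna, phi_rna = phi_rna,
               activity_noise_sd = activity_noise_sd,
               within_block_correlation = within_block_correlation,
               paired = paired, seed = seed)
  .validate_spec(spec)
  structure(spec, class = "simulation_spec")
}

.validate_spec <- function(s) {
  if (s$n_elements < 1 || s$barcodes_per_element < 1)
    stop("spec error: n_elements and barcodes_per_element must be >= 1")
  if (length(s$samples_per_group) != 2L || any(s$samples_per_group < 1))
    stop("spec error: samples_per_group must be c(n1, n2) with n >= 1")
  if (s$dna_lib_size <= 0 || s$rna_lib_size <= 0)
    stop("spec error: library sizes must be positive")
  if (s$effect_fraction < 0 || s$effect_fraction > 1)
    stop("spec error: effect_fraction must be in [0, 1]")
  if (s$phi_dna < 0 || s$phi_rna < 0)
    stop("spec error: overdispersions must be >= 0")
  if (s$within_block_correlation < 0 || s$within_block_correlation > 1)
    stop("spec error: within_block_correlation must be in [0, 1]")
  if (s$paired && s$samples_per_group[1] != s$samples_per_group[2])
    stop("spec error: paired designs need equal group sizes")
  invisible(TRUE)
}

# NB draw with variance (1 + phi * mu) * mu; phi = 0 is Poisson.
.rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Generate a synthetic MPRA dataset
#'
#' Draws barcode-level DNA and RNA counts under the negative-binomial model
#' described in [simulation_spec()], together with a truth table recording
#' each element's true activities and differential status.
#'
#' @param spec a [simulation_spec()].
#' @return List with `counts` (a [BarcodeCountSet]; sample sheet has
#'   `condition` = group1/group2 and, for paired specs, a `block` column)
#'   and `truth` (`data.frame`: `element_id`, `a_group1`, `a_group2`,
#'   `is_differential`).
#' @export
generate_mpra <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  nE <- spec$n_elements
  B <- spec$barcodes_per_element
  n1 <- spec$samples_per_group[1]
  n2 <- spec$samples_per_group[2]
  nS <- n1 + n2
  group <- rep(c("group1", "group2"), c(n1, n2))

  meanlog <- log(1 / nE) - spec$copy_number_sdlog^2 / 2
  p_d <- stats::rlnorm(nE, meanlog, spec$copy_number_sdlog)
  a1 <- stats::rnorm(nE, spec$activity_mean, spec$activity_sd)
  n_diff <- round(spec$effect_fraction * nE)
  is_diff <- rep(FALSE, nE)
  if (n_diff > 0) is_diff[sample.int(nE, n_diff)] <- TRUE
  a2 <- a1 + ifelse(is_diff, spec$effect_size, 0)

  # biological activity noise, optionally correlated within blocks
  noise <- matrix(0, nE, nS)
  if (spec$activity_noise_sd > 0) {
    rho <- if (spec$paired) spec$within_block_correlation else 0
    sd_u <- spec$activity_noise_sd * sqrt(rho)
    sd_v <- spec$activity_noise_sd * sqrt(1 - rho)
    if (spec$paired && rho > 0) {
      u <- matrix(stats::rnorm(nE * n1, 0, sd_u), nE, n1)
      noise <- u[, c(seq_len(n1), seq_len(n2)), drop = FALSE]
    }
    noise <- noise + matrix(stats::rnorm(nE * nS, 0, sd_v), nE, nS)
  }
  a_mat <- cbind(matrix(a1, nE, n1), matrix(a2, nE, n2)) + noise

  mu_d <- spec$dna_lib_size * p_d / B  # per barcode
  elem <- rep(seq_len(nE), each = B)
  dna <- matrix(0L, nE * B, nS)
  rna <- matrix(0L, nE * B, nS)
  depth_ratio <- spec$rna_lib_size / spec$dna_lib_size
  for (s in seq_len(nS)) {
    mud <- mu_d[elem]
    dna[, s] <- .rnb(nE * B, mud, spec$phi_dna)
    mur <- mud * 2^a_mat[elem, s] * depth_ratio
    rna[, s] <- .rnb(nE * B, mur, spec$phi_rna)
  }
  element_ids <- sprintf("elem_%04d", seq_len(nE))
  rownames(dna) <- rownames(rna) <-
    paste0(element_ids[elem], "_bc", rep(seq_len(B), nE))
  sample_ids <- c(paste0("g1_s", seq_len(n1)), paste0("g2_s", seq_len(n2)))
  colnames(dna) <- colnames(rna) <- sample_ids
  samples <- data.frame(sample_id = sample_ids, condition = group,
                        stringsAsFactors = FALSE)
  if (spec$paired)
    samples$block <- paste0("pair", c(seq_len(n1), seq_len(n2)))
  counts <- BarcodeCountSet(rna, dna, element = element_ids[elem],
                            samples = samples)
  truth <- data.frame(element_id = element_ids, a_group1 = a1, a_group2 = a2,
                      is_differential = is_diff, p_dna = p_d,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth, spec = spec)
}

#' Null-resample an MPRA dataset
#'
#' Builds a synthetic dataset in which every element is truly null while
#' preserving each element's observed mean activity and residual spread.
#' The procedure: (1) compute element-level log-ratio activity measures;
#' (2) save the element-wise residual SDs after group-centering, and the
#' group-1 means; (3) standardize the log-ratios within each group to mean
#' zero and unit variance; (4) permute the standardized residuals without
#' replacement within each element across samples (for paired designs,
#' allele pairs are permuted jointly); (5) rescale by the saved SDs and add
#' the group-1 means to both groups; (6) retain the original DNA counts;
#' (7) reconstruct RNA counts from the original DNA counts and the
#' resampled log-ratios, rounded to the nearest non-negative integer and
#' allocated to barcodes in proportion to each element's original barcode
#' RNA fractions; (8) the original DNA and new RNA counts form the null
#' dataset.
#'
#' @param counts a [BarcodeCountSet] with a two-level `condition`.
#' @param paired permute allele/sample pairs jointly using the sample-sheet
#'   `block` column.
#' @param seed integer seed; permutations are drawn from a stream keyed by
#'   `(seed, element index)` so results do not depend on element order.
#' @return A [BarcodeCountSet] with identical DNA counts and resampled RNA
#'   counts.
#' @export
null_resample <- function(counts, paired = FALSE, seed = 1) {
  stopifnot(inherits(counts, "BarcodeCountSet"))
  counts <- .require_norm(counts)
  cond <- counts$samples$condition
  if (nlevels(cond) != 2L)
    stop("design error: null resampling needs exactly two comparison groups")
  if (any(table(cond) < 2L))
    stop("degenerate input: each group needs >= 2 samples")
  g1 <- which(cond == levels(cond)[1])
  g2 <- which(cond == levels(cond)[2])
  act <- summarize_dataset(counts, "aggregate")
  Y <- act$activity
  nE <- nrow(Y)

  m1 <- rowMeans(Y[, g1, drop = FALSE])
  m2 <- rowMeans(Y[, g2, drop = FALSE])
  cent <- Y
  cent[, g1] <- Y[, g1] - m1
  cent[, g2] <- Y[, g2] - m2
  df <- ncol(Y) - 2L
  sd_resid <- sqrt(rowSums(cent^2) / df)

  sd1 <- pmax(apply(Y[, g1, drop = FALSE], 1L, stats::sd), 1e-8)
  sd2 <- pmax(apply(Y[, g2, drop = FALSE], 1L, stats::sd), 1e-8)
  Z <- Y
  Z[, g1] <- (Y[, g1] - m1) / sd1
  Z[, g2] <- (Y[, g2] - m2) / sd2

  if (paired) {
    blk <- counts$samples$block
    if (is.null(blk)) stop("design error: paired resampling needs a block column")
    blk <- as.factor(blk)
    pair_members <- split(seq_along(blk), blk)
  }
  nS <- ncol(Y)
  Zp <- Z
  for (e in seq_len(nE)) {
    set.seed((seed * 48271 + e) %% 2147483647L)
    if (paired) {
      perm_blocks <- sample(length(pair_members))
      for (k in seq_along(pair_members)) {
        Zp[e, pair_members[[k]]] <- Z[e, pair_members[[perm_blocks[k]]]]
      }
    } else {
      Zp[e, ] <- Z[e, sample(nS)]
    }
  }
  Ynew <- m1 + sd_resid * Zp  # both groups get the saved group-1 means

  # reconstruct RNA from original DNA and the resampled log-ratios
  dagg <- rowsum(counts$dna, group = counts$element, reorder = FALSE)
  dagg <- dagg[act$element_ids, , drop = FALSE]
  rna_new <- counts$rna
  rna_new[] <- 0L
  eidx <- split(seq_along(counts$element),
                factor(counts$element, levels = act$element_ids))
  for (s in seq_len(nS)) {
    target <- ((1 + counts$dna_sf[s] * dagg[, s]) * 2^Ynew[, s] - 1) /
      counts$rna_sf[s]
    target <- pmax(0, round(target))
    for (e in seq_len(nE)) {
      rows <- eidx[[e]]
      orig <- counts$rna[rows, s]
      frac <- if (sum(orig) > 0) orig / sum(orig)
              else rep(1 / length(rows), length(rows))
      rna_new[rows, s] <- .allocate_integer(target[e], frac)
    }
  }
  # keep the original library sizes: the log-ratios were reconstructed under
  # the original scale factors, so reusing them makes the procedure exact
  BarcodeCountSet(rna_new, counts$dna, element = counts$element,
                  samples = counts$samples,
                  rna_lib_sizes = counts$rna_lib_sizes,
                  dna_lib_sizes = counts$dna_lib_sizes)
}

# split integer total over categories by fractions, largest-remainder rule
.allocate_integer <- function(total, frac) {
  raw <- total * frac
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
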