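test_that("simulation specs are validated", {
  expect_s3_class(simulation_spec(), "simulation_spec")
  expect_error(simulation_spec(effect_fraction = 1.5), "spec error")
  expect_error(simulation_spec(phi_dna = -1), "spec error")
  expect_error(simulation_spec(samples_per_group = c(3)), "spec error")
  expect_error(simulation_spec(paired = TRUE, samples_per_group = c(3, 4)),
               "spec error")
})

test_that("generator is reproducible and honors the count model", {
  spec <- simulation_spec(n_elements = 50, seed = 9)
  s1 <- generate_mpra(spec)
  s2 <- generate_mpra(spec)
  expect_identical(s1$counts$rna, s2$counts$rna)
  expect_identical(s1$counts$dna, s2$counts$dna)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_mpra(simulation_spec(n_elements = 50, seed = 10))
  expect_false(identical(s1$counts$rna, s3$counts$rna))

  # truth table marks the requested fraction of differential elements
  sd <- generate_mpra(simulation_spec(n_elements = 200, effect_fraction = 0.1,
                                      effect_size = 1, seed = 2))
  expect_equal(sum(sd$truth$is_differential), 20)
  expect_equal(sd$truth$a_group2 - sd$truth$a_group1,
               ifelse(sd$truth$is_differential, 1, 0))
})

test_that("phi = 0 gives Poisson DNA counts (index of dispersion 1)", {
  spec <- simulation_spec(n_elements = 400, barcodes_per_element = 10,
                          phi_dna = 0, phi_rna = 0, activity_sd = 0,
                          seed = 3)
  sim <- generate_mpra(spec)
  d <- sim$counts$dna
  el <- sim$counts$element
  # per element, pooled barcode x sample draws share one mean
  ids <- unique(el)
  idx <- mean(vapply(ids, function(e) {
    v <- as.numeric(d[el == e, ])
    var(v) / mean(v)
  }, numeric(1)))
  n_per <- 10 * ncol(d)
  mc_se <- sqrt(2 / (n_per - 1)) / sqrt(length(ids))
  expect_lt(abs(idx - 1), 3 * mc_se)
})

test_that("generated moments match the spec", {
  spec <- simulation_spec(n_elements = 10000, barcodes_per_element = 2,
                          samples_per_group = c(4, 4), activity_sd = 0,
                          seed = 4)
  sim <- generate_mpra(spec)
  d <- sim$counts$dna
  # pooled mean per barcode is N_d * E[p_d] / B = N_d / (n_elements * B)
  expect_lt(abs(mean(d) / (spec$dna_lib_size / (10000 * 2)) - 1), 0.05)
  # average within-element variance matches (1 + phi mu_e) mu_e at the
  # realized per-element copy numbers recorded in the truth table
  el <- sim$counts$element
  v_obs <- vapply(split(seq_along(el), el), function(i)
    var(as.numeric(d[i, ])), numeric(1))
  mu_e <- spec$dna_lib_size * sim$truth$p_dna / 2
  v_th <- (1 + spec$phi_dna * mu_e) * mu_e
  ord <- match(names(v_obs), sim$truth$element_id)
  expect_lt(abs(mean(v_obs) / mean(v_th[ord]) - 1), 0.05)
})

test_that("overdispersed data reproduce the decreasing variance trend", {
  sim <- generate_mpra(simulation_spec(n_elements = 800, seed = 5))
  act <- summarize_dataset(total_count_normalize(sim$counts))
  prof <- empirical_sd_profile(act)
  lw <- lowess(prof$mean_log2_dna, prof$sd, f = 0.3)
  # local-average variability falls from the low-DNA to the high-DNA end
  expect_gt(mean(head(lw$y, 50)), mean(tail(lw$y, 50)))
  expect_lt(unname(coef(lm(sd ~ mean_log2_dna, prof))[2]), 0)
})

test_that("null resampling preserves DNA, residual multisets and means", {
  sim <- generate_mpra(simulation_spec(n_elements = 150, effect_fraction = 0.2,
                                       effect_size = 1, seed = 6))
  counts <- sim$counts
  nulls <- null_resample(counts, seed = 2)

  # step 6: DNA identical
  expect_identical(nulls$dna, counts$dna)

  # reconstructed activities: element-wise mean over all samples equals the
  # saved group-1 mean, up to RNA integer rounding
  cn <- total_count_normalize(counts)
  act <- summarize_dataset(cn)$activity
  g1 <- which(counts$samples$condition == "group1")
  m1 <- rowMeans(act[, g1, drop = FALSE])
  actn <- summarize_dataset(total_count_normalize(nulls))$activity
  expect_lt(max(abs(rowMeans(actn) - m1)), 0.05)

  # standardized-residual multisets are permutations, not redraws: the
  # output activities are m1 + sd_res * permuted(z), so the sorted rescaled
  # residuals must coincide with the sorted originals up to count rounding
  g2 <- which(counts$samples$condition == "group2")
  cent <- act
  cent[, g1] <- act[, g1] - m1
  cent[, g2] <- act[, g2] - rowMeans(act[, g2, drop = FALSE])
  sd_res <- sqrt(rowSums(cent^2) / (ncol(act) - 2))
  sd1 <- pmax(apply(act[, g1, drop = FALSE], 1, sd), 1e-8)
  sd2 <- pmax(apply(act[, g2, drop = FALSE], 1, sd), 1e-8)
  z_old <- act
  z_old[, g1] <- (act[, g1] - m1) / sd1
  z_old[, g2] <- (act[, g2] - rowMeans(act[, g2, drop = FALSE])) / sd2
  mism <- vapply(seq_len(nrow(act)), function(e) {
    max(abs(sort(actn[e, ] - m1[e]) - sort(sd_res[e] * z_old[e, ])))
  }, numeric(1))
  expect_true(all(is.finite(mism)))
  expect_lt(stats::median(mism), 0.05)

  # same seed reproduces, different seed permutes differently
  expect_identical(null_resample(counts, seed = 2)$rna, nulls$rna)
  expect_false(identical(null_resample(counts, seed = 3)$rna, nulls$rna))

  expect_error(null_resample(
    generate_mpra(simulation_spec(n_elements = 20,
                                  samples_per_group = c(1, 1),
                                  seed = 1))$counts), "degenerate|two")
})

test_that("paired resampling keeps allele pairs together", {
  sim <- generate_mpra(simulation_spec(n_elements = 60, paired = TRUE,
                                       activity_noise_sd = 0.3,
                                       within_block_correlation = 0.5,
                                       seed = 7))
  nulls <- null_resample(sim$counts, paired = TRUE, seed = 1)
  expect_identical(nulls$dna, sim$counts$dna)
  expect_identical(nulls$samples$block, sim$counts$samples$block)
})
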