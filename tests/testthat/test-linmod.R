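test_that("weighted least squares matches the normal-equations oracle", {
  # unit weights, two groups with means 1 and 3: difference coefficient 2
  y <- c(1, 1, 1, 3, 3, 3)
  X <- two_group_design(3, 3)
  fit <- wls_fit(y, rep(1, 6), X)
  expect_equal(unname(fit$coefficients), c(1, 2))
  expect_equal(fit$sigma, 0)
  expect_equal(fit$df_residual, 4)

  # y identically zero
  fit0 <- wls_fit(rep(0, 6), runif(6, 0.5, 2), X)
  expect_equal(unname(fit0$coefficients), c(0, 0))
  expect_equal(fit0$sigma, 0)

  # arbitrary weights vs explicit (X'WX)^-1 X'Wy solve
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    X <- cbind(1, rnorm(n), runif(n))
    y <- rnorm(n)
    w <- runif(n, 0.2, 5)
    fit <- wls_fit(y, w, X)
    W <- diag(w)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-10)
    covb <- solve(t(X) %*% W %*% X)
    expect_equal(unname(fit$stdev_unscaled), sqrt(diag(covb)),
                 tolerance = 1e-10)
    rss <- t(y - X %*% beta) %*% W %*% (y - X %*% beta)
    expect_equal(fit$sigma, sqrt(drop(rss) / (n - 3)), tolerance = 1e-10)
  }

  expect_error(wls_fit(y <- rnorm(4), rep(1, 4), cbind(1, c(1, 1, 1, 1))),
               "rank deficient")
})

test_that("generalized least squares matches a whitened-regression oracle", {
  set.seed(2)
  n1 <- 4
  X <- two_group_design(n1, n1)
  blk <- factor(rep(1:n1, 2))
  for (rho in c(0.3, 0.5, 0.8)) {
    y <- rnorm(2 * n1)
    w <- runif(2 * n1, 0.5, 2)
    fit <- gls_fit(y, w, X, blk, rho)
    # brute-force: build Sigma, whiten with its Cholesky root
    C <- diag(2 * n1)
    for (b in levels(blk)) {
      i <- which(blk == b)
      C[i[1], i[2]] <- C[i[2], i[1]] <- rho
    }
    Sigma <- C * outer(1 / sqrt(w), 1 / sqrt(w))
    Si <- solve(Sigma)
    beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
    expect_equal(unname(fit$coefficients), unname(drop(beta)), tolerance = 1e-10)
    covb <- solve(t(X) %*% Si %*% X)
    expect_equal(unname(fit$stdev_unscaled), unname(sqrt(diag(covb))),
                 tolerance = 1e-10)
  }

  # rho = 0 reduces exactly to WLS
  y <- rnorm(2 * n1); w <- runif(2 * n1, 0.5, 2)
  expect_equal(gls_fit(y, w, X, blk, 0)$coefficients,
               wls_fit(y, w, X)$coefficients, tolerance = 1e-12)

  # SE of the group-difference coefficient shrinks as rho -> 1
  ses <- sapply(seq(0, 0.95, by = 0.05), function(r)
    gls_fit(y, w, X, blk, r)$stdev_unscaled[2])
  expect_true(all(diff(ses) < 0))
})

test_that("variance moderation follows the posterior formula and edge cases", {
  # frozen arithmetic: d0=4, s0^2=2, d=4, s^2=6 -> (8 + 24)/8 = 4
  expect_equal((4 * 2 + 4 * 6) / (4 + 4), 4.0)
  sq <- squeeze_var(c(6, 6.0001), c(4, 4))
  expected <- if (is.infinite(sq$df_prior)) rep(sq$s2_prior, 2) else
    (sq$df_prior * sq$s2_prior + 4 * c(6, 6.0001)) / (sq$df_prior + 4)
  expect_equal(sq$s2_post, expected)

  # identical variances: degenerate prior, posterior equals the common value
  sq2 <- squeeze_var(rep(3.5, 10), 4)
  expect_equal(sq2$df_prior, Inf)
  expect_equal(sq2$s2_prior, 3.5)
  expect_equal(sq2$s2_post, rep(3.5, 10))

  # moderation shrinks towards the prior, element-wise
  set.seed(3)
  s2 <- exp(rnorm(500, 0, 0.7))
  sq3 <- squeeze_var(s2, 4)
  expect_true(all(abs(sq3$s2_post - sq3$s2_prior) <=
                  abs(s2 - sq3$s2_prior) + 1e-12))

  expect_error(squeeze_var(3, 4), "insufficient")
})

test_that("moderation agrees with an independent empirical-Bayes fit", {
  set.seed(4)
  d0 <- 8; s02 <- 1.5; d <- 5; m <- 3000
  sigma2 <- s02 * d0 / rchisq(m, d0)
  s2 <- sigma2 * rchisq(m, d) / d
  mine <- squeeze_var(s2, d)
  ref <- limma::squeezeVar(s2, d)
  expect_equal(mine$df_prior, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine$s2_prior, ref$var.prior, tolerance = 1e-6)
  expect_equal(mine$s2_post, ref$var.post, tolerance = 1e-6)
})

test_that("moderated t is calibrated and honors contrasts", {
  set.seed(5)
  m <- 5000; X <- two_group_design(3, 3)
  Y <- matrix(rnorm(m * 6), m, 6)
  fits <- lapply(seq_len(m), function(e) wls_fit(Y[e, ], rep(1, 6), X))
  fit <- list(coefficients = t(vapply(fits, `[[`, numeric(2), "coefficients")),
              stdev_unscaled = t(vapply(fits, `[[`, numeric(2),
                                        "stdev_unscaled")),
              cov_unscaled = array(vapply(fits, `[[`, matrix(0, 2, 2),
                                          "cov_unscaled"), c(2, 2, m)),
              sigma = vapply(fits, `[[`, numeric(1), "sigma"),
              df_residual = vapply(fits, `[[`, numeric(1), "df_residual"))
  sq <- squeeze_var(fit$sigma^2, fit$df_residual)
  fit$df_prior <- sq$df_prior; fit$s2_post <- sq$s2_post
  tab <- moderated_t(fit, coef = 2)

  # fully null: p values uniform
  expect_lt(unname(stats::ks.test(tab$p_value, "punif")$statistic), 0.02)

  # identity contrast equals the per-coefficient test
  tab_c <- moderated_t(fit, contrast = c(0, 1))
  expect_equal(tab_c$t, tab$t)
  expect_equal(tab_c$p_value, tab$p_value)

  # beta = 0 gives t = 0, p = 1
  fit$coefficients[1, ] <- 0
  tab0 <- moderated_t(fit, coef = 2)
  expect_equal(tab0$t[1], 0)
  expect_equal(tab0$p_value[1], 1)

  expect_error(moderated_t(fit, contrast = c(1, 0, 0)), "contrast error")
})

test_that("consensus correlation recovers known block correlation", {
  set.seed(6)
  nE <- 800; n1 <- 4
  X <- two_group_design(n1, n1)
  blk <- factor(rep(1:n1, 2))
  make_y <- function(rho) {
    t(vapply(seq_len(nE), function(e) {
      u <- rnorm(n1, 0, sqrt(rho))
      c(u, u) + rnorm(2 * n1, 0, sqrt(1 - rho)) + rep(c(0, 1), each = n1)
    }, numeric(2 * n1)))
  }
  W <- matrix(1, nE, 2 * n1)
  r5 <- estimate_consensus_correlation(make_y(0.5), W, X, blk)
  expect_lt(abs(r5 - 0.5), 0.1)
  r0 <- estimate_consensus_correlation(make_y(0), W, X, blk)
  expect_lt(abs(r0), 0.1)

  # independent cross-check against limma's consensus estimator
  Y <- make_y(0.5)
  ref <- limma::duplicateCorrelation(Y, design = X,
                                     block = blk)$consensus.correlation
  expect_equal(r5, ref, tolerance = 0.05)

  # perfectly duplicated samples within blocks: near-unit correlation
  half <- matrix(rnorm(nE * n1), nE, n1)
  Ydup <- half[, c(1:n1, 1:n1)] + matrix(rnorm(nE * 2 * n1, 0, 1e-3),
                                         nE, 2 * n1)
  expect_gt(estimate_consensus_correlation(Ydup, W, cbind(1, rep(0:1, each = n1)),
                                           blk), 0.9)

  expect_error(estimate_consensus_correlation(Y, W, X, NULL), "design error")
})

test_that("the full fit is deterministic and null-faithful", {
  set.seed(7)
  sim <- generate_mpra(simulation_spec(n_elements = 80, seed = 11))
  # duplicated columns across groups: difference coefficients exactly 0
  cts <- sim$counts
  n1 <- 4
  cts$rna[, 5:8] <- cts$rna[, 1:4]
  cts$dna[, 5:8] <- cts$dna[, 1:4]
  cts$rna_lib_sizes <- colSums(cts$rna)
  cts$dna_lib_sizes <- colSums(cts$dna)
  fit <- mpralm(cts, ~ condition)
  expect_equal(max(abs(fit$coefficients[, 2])), 0)

  # re-running gives bitwise-identical p values
  fit1 <- mpralm(sim$counts, ~ condition)
  fit2 <- mpralm(sim$counts, ~ condition)
  expect_identical(fit1$p_value, fit2$p_value)

  # accessors are mutually consistent
  expect_equal(coef(fit1), fit1$coefficients)
  expect_equal(residuals(fit1),
               fit1$activity$activity - fitted(fit1))
})

test_that("true effects rank ahead of nulls on moderately dispersed data", {
  sim <- generate_mpra(simulation_spec(
    n_elements = 200, effect_fraction = 0.1, effect_size = 1,
    phi_dna = 0.2, phi_rna = 0.2,
    dna_lib_size = 1e6, rna_lib_size = 1e6, seed = 1))
  fit <- mpralm(sim$counts, ~ condition)
  tab <- top_elements(fit, sort_by = "none")
  lab <- sim$truth$is_differential[match(tab$element_id,
                                         sim$truth$element_id)]
  frac_top <- mean(rank(tab$p_value)[lab] <= 0.1 * nrow(tab))
  expect_gt(frac_top, 0.7)
})
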