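test_that("marker dosage variance reproduces the two-ancestry closed form", {
  mom <- moments_fixed(c(0.5, 0.5))
  expect_equal(var_att_marker(mom, c(0.2, 0.8)), 0.5)
  # equal frequencies: heterogeneity term vanishes
  expect_equal(var_att_marker(moments_dirichlet(c(8, 2)), c(0.3, 0.3)),
               2 * 0.3 * 0.7)
  # single ancestry
  expect_equal(var_att_marker(moments_fixed(c(1, 0)), c(0.4, 0.9)),
               2 * 0.4 * 0.6)
  expect_error(psd_moments(c(0.5, 0.4), diag(2) / 2), "sum to 1")
})

test_that("partitioned-dosage covariance is diagonal and matches simulation", {
  mom <- moments_fixed(c(0.5, 0.5))
  V <- var_tractor_matrix(mom, c(0.2, 0.8))
  expect_equal(V, diag(c(0.16, 0.16)))
  expect_lte(sum(diag(V)), var_att_marker(mom, c(0.2, 0.8)))

  # Monte-Carlo: centered partitioned dosages over PSD draws
  n <- 1e5
  g <- c(0.2, 0.8)
  co <- simulate_psd_cohort(n, matrix(g, 2, 1), dirichlet = c(4, 4),
                            seed = 31, maf_min = 0)
  cnt <- la_counts(co$la)[, , 1]
  Mt <- co$geno$partitioned[, , 1] - sweep(cnt, 2, g, `*`)
  emp <- crossprod(Mt) / n
  momd <- moments_dirichlet(c(4, 4))
  pred <- var_tractor_matrix(momd, g)
  expect_lt(max(abs(emp - pred)), 3 * 0.5 / sqrt(n) + 0.003)
  expect_lt(abs(emp[1, 2]), 3 * 0.3 / sqrt(n) + 0.003)
})

test_that("predicted standard errors follow the variance formula", {
  expect_equal(predicted_se("att", moments_fixed(c(1, 0)), c(0.5, 0.5), 1,
                            5000), 0.02)
  # ancestry-specific SE = single-continental SE / sqrt(E[P_l])
  mom <- moments_fixed(c(0.25, 0.75))
  g <- c(0.3, 0.3)
  se_single <- predicted_se("att", moments_fixed(c(1, 0)), g, 1, 1000)
  se_l <- predicted_se("tractor", mom, g, 1, 1000, ancestry = 1)
  expect_equal(se_l, se_single / sqrt(0.25), tolerance = 1e-12)
  expect_error(predicted_se("att", mom, c(0, 0), 1, 100), "monomorphic")
})

test_that("expected Wald limits are ordered for every valid input", {
  out <- expected_statistics(1, moments_fixed(c(0.5, 0.5)), c(0.2, 0.8), 1)
  expect_equal(out$per_ancestry, c(0.16, 0.16))
  expect_equal(out$combined, 0.32)
  expect_equal(out$att, 0.5)
  expect_equal(expected_statistics(0, moments_fixed(c(0.5, 0.5)),
                                   c(0.2, 0.8), 1)$att, 0)
  # equality when frequencies coincide
  eq <- expected_statistics(1, moments_dirichlet(c(8, 2)), c(0.4, 0.4), 1)
  expect_equal(eq$combined, eq$att, tolerance = 1e-12)

  # property: ordering over random simplex moments and frequencies
  set.seed(32)
  for (r in 1:200) {
    conc <- runif(2, 0.2, 20)
    g <- runif(2, 0.01, 0.99)
    o <- expected_statistics(runif(1, -2, 2), moments_dirichlet(conc), g, 1)
    expect_lte(max(o$per_ancestry), o$combined + 1e-12)
    expect_lte(o$combined, o$att + 1e-12)
  }
})

test_that("extended-PSD marginal and LA coefficients match the closed forms", {
  # marker = causal variant: weight 1, beta = alpha
  g <- c(0.3, 0.6)
  ldp <- ld_params(f = cbind(g), g = g, h = cbind(g))
  expect_equal(beta_tractor_epsd(ldp, 0.7), rep(0.7, 2))
  expect_equal(gamma_tractor_epsd(ldp, 0.7), 0)

  # two causal loci arithmetic
  ld2 <- ld_params(f = matrix(0.5, 2, 2), g = c(0.5, 0.5),
                   h = matrix(c(0.33, 0.25, 0.21, 0.25), 2, 2))
  # ancestry 1: D = (0.08, -0.04), weights over g(1-g)=0.25
  expect_equal(beta_tractor_epsd(ld2, c(1, 0.5))[1], 0.24)

  # worked LA coefficient
  ld3 <- ld_params(f = cbind(c(0.3, 0.3)), g = c(0.3, 0.3),
                   h = cbind(c(0.3, 0.25)))
  expect_equal(gamma_tractor_epsd(ld3, 1), 0.05 / 0.7)
  expect_equal(gamma_tractor_epsd(ld3, 0), 0)

  expect_error(ld_params(cbind(c(0.3, 0.3)), c(0.3, 0.3),
                         cbind(c(0.5, 0.3))), "Frechet")
})

test_that("standard-GWAS marginal effect recovers alpha at the causal marker", {
  mom <- moments_dirichlet(c(8, 2))
  g <- c(0.25, 0.65)
  ldp <- ld_params(f = cbind(g), g = g, h = cbind(g))
  expect_equal(beta_att_epsd(ldp, 0.8, mom, dist_M = 0, gens = 12), 0.8,
               tolerance = 1e-12)
  # remote causal variant with no within-continental LD contributes nothing
  ld0 <- ld_params(f = cbind(c(0.4, 0.4)), g = g,
                   h = cbind(c(0.4 * 0.25, 0.4 * 0.65)))
  expect_equal(beta_att_epsd(ld0, 1, mom, dist_M = 10, gens = 12), 0,
               tolerance = 1e-10)
  # equal frequencies + no admixture LD: reduces to the within-LD weight
  ldq <- ld_params(f = cbind(c(0.5, 0.5)), g = c(0.5, 0.5),
                   h = cbind(c(0.33, 0.29)))
  b_att <- beta_att_epsd(ldq, 1, mom, dist_M = 1e6, gens = 12)
  b_l <- beta_tractor_epsd(ldq, 1)
  expect_equal(b_att, sum(b_l * mom$EP), tolerance = 1e-10)
})

test_that("single-pulse LA covariance matches the mosaic ancestry process", {
  expect_equal(la_covariance_pulse(c(0.5, 0.5), 1, 1, 0, 12), 0.25)
  expect_equal(la_covariance_pulse(c(0.5, 0.5), 1, 2, 0, 12), -0.25)
  d <- 0.05
  pred <- la_covariance_pulse(c(0.5, 0.5), 1, 1, d, 12)
  expect_equal(pred, 0.25 * exp(-0.6), tolerance = 1e-12)

  # Monte-Carlo over the Poisson-breakpoint ancestry process
  set.seed(33)
  nrep <- 2e4
  x <- z <- numeric(nrep)
  for (r in seq_len(nrep)) {
    nb <- rpois(1, 12 * d)
    a0 <- rbinom(1, 1, 0.5)
    a1 <- if (nb == 0) a0 else rbinom(1, 1, 0.5)
    x[r] <- a0; z[r] <- a1
  }
  emp <- mean(x * z) - mean(x) * mean(z)
  expect_lt(abs(emp - pred), 3 * sd(x * z) / sqrt(nrep))
})

test_that("LD weight / correlation conversions are exact", {
  expect_equal(epsd_ld_weight(0.25, 0.5), 1)
  expect_equal(epsd_ld_corr(0.25, 0.5, 0.5), 1)
  expect_equal(epsd_ld_weight(0, 0.3), 0)
  expect_equal(epsd_ld_weight(0.08, 0.5), 0.32)
  expect_equal(epsd_ld_corr(0.08, 0.5, 0.5), 0.32)
  expect_error(epsd_ld_weight(0.1, 1), "boundary")
})

test_that("effective-sample-size factors follow sqrt(E[P])", {
  f <- effective_n_factor(1)
  expect_equal(unlist(f), c(se_inflation = 1, z_deflation = 1,
                            n_multiplier = 1))
  expect_equal(effective_n_factor(0.25)$z_deflation, 0.5)
  expect_equal(effective_n_factor(0.25)$se_inflation, 2)
  expect_error(effective_n_factor(0), "\\(0, 1\\]")
})
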