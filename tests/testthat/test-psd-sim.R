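test_that("global ancestry: fixed and degenerate specs give exact rows", {
  P <- draw_global_ancestry(3, fixed = c(0.8, 0.2))
  expect_equal(dim(P), c(3L, 2L))
  expect_true(all(P[, 1] == 0.8) && all(P[, 2] == 0.2))
  expect_identical(attr(P, "source"), "fixed")

  P1 <- draw_global_ancestry(5, fixed = c(1, 0))
  expect_true(all(P1[, 1] == 1))

  expect_error(draw_global_ancestry(2, fixed = c(0.5, 0.4)), "sum")
  expect_error(draw_global_ancestry(2, dirichlet = c(2, 0)), "positive")
  expect_error(draw_global_ancestry(2, fixed = c(0.5, 0.5),
                                    dirichlet = c(1, 1)), "exactly one")
})

test_that("dirichlet global ancestry has the right column means", {
  n <- 1e5
  P <- draw_global_ancestry(n, dirichlet = c(8, 2), seed = 42)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  # Dirichlet(8,2): mean (0.8, 0.2), var p(1-p)/(a0+1)
  mc_se <- sqrt(0.8 * 0.2 / 11 / n)
  expect_lt(abs(mean(P[, 1]) - 0.8), 3 * mc_se)
})

test_that("local ancestry counts always sum to 2 and respect degenerate P", {
  P <- draw_global_ancestry(4, fixed = c(1, 0))
  la <- draw_local_ancestry(P, 7, seed = 1)
  expect_true(all(la$hap == 1L))
  cnt <- la_counts(la)
  expect_true(all(cnt[, 1, ] == 2L) && all(cnt[, 2, ] == 0L))

  P2 <- draw_global_ancestry(50, dirichlet = c(3, 2, 1), seed = 2)
  la2 <- draw_local_ancestry(P2, 20, seed = 3)
  expect_true(all(apply(la_counts(la2), c(1, 3), sum) == 2))
  expect_true(all(la2$hap %in% 1:3))
  expect_error(draw_local_ancestry(P2, 0), "positive")
})

test_that("local ancestry draws have the multinomial mean", {
  P <- draw_global_ancestry(1, fixed = c(0.5, 0.5))
  la <- draw_local_ancestry(P, 1e5, seed = 9)
  L1 <- la_counts(la)[1, 1, ]
  mc_se <- sqrt(0.5 / 1e5)  # Var(L1) = 2 * 0.5 * 0.5
  expect_lt(abs(mean(L1) - 1), 3 * mc_se)
})

test_that("alleles follow the labelled ancestry's frequency", {
  P <- draw_global_ancestry(100, dirichlet = c(2, 2), seed = 4)
  la <- draw_local_ancestry(P, 10, seed = 5)
  g <- draw_genotypes(la, matrix(c(1, 0), 2, 10), seed = 6)
  expect_true(all(g$hap[la$hap == 1L] == 1L))
  expect_true(all(g$hap[la$hap == 2L] == 0L))

  # single-ancestry realized frequency
  P1 <- draw_global_ancestry(500, fixed = c(1, 0))
  la1 <- draw_local_ancestry(P1, 100, seed = 7)
  g1 <- draw_genotypes(la1, matrix(c(0.3, 0.9), 2, 100), seed = 8)
  nhl <- 500 * 2 * 100
  expect_lt(abs(mean(g1$hap) - 0.3), 3 * sqrt(0.3 * 0.7 / nhl))

  # HWE within the single-ancestry stratum
  tab <- tabulate(g1$dosage[, 1] + 1L, 3) / 500
  expect_lt(max(abs(tab - c(0.49, 0.42, 0.09))), 3 * sqrt(0.5 / 500) + 0.02)

  expect_error(draw_genotypes(la1, matrix(0.3, 1, 99), seed = 1), "loci")
})

test_that("partitioned dosages reproduce the worked heterozygote cases", {
  la <- make_la(array(c(1L, 2L), dim = c(1, 2, 1)))
  # both copies carry the reference allele
  g <- make_geno(array(c(1L, 1L), dim = c(1, 2, 1)))
  pg <- partition_dosage(g, la)
  expect_equal(pg$partitioned[1, , 1], c(1L, 1L))
  expect_equal(pg$dosage[1, 1], 2L)
  # only the first-ancestry copy carries it
  g2 <- make_geno(array(c(1L, 0L), dim = c(1, 2, 1)))
  pg2 <- partition_dosage(g2, la)
  expect_equal(pg2$partitioned[1, , 1], c(1L, 0L))
  # homozygous-ancestry, no reference alleles
  la3 <- make_la(array(c(1L, 1L), dim = c(1, 2, 1)))
  g3 <- make_geno(array(c(0L, 0L), dim = c(1, 2, 1)))
  expect_equal(partition_dosage(g3, la3)$partitioned[1, , 1], c(0L, 0L))

  expect_error(partition_dosage(g3, la), NA)
  bad_la <- make_la(array(1L, dim = c(2, 2, 1)))
  expect_error(partition_dosage(g3, bad_la), "shape")
})

test_that("simulated cohorts satisfy the count and dominance invariants", {
  freqs <- matrix(runif(40, 0.2, 0.8), 2, 20)
  co <- simulate_psd_cohort(300, freqs, dirichlet = c(8, 2), seed = 11)
  cnt <- la_counts(co$la)
  expect_true(all(apply(cnt, c(1, 3), sum) == 2))
  expect_true(all(apply(co$geno$partitioned, c(1, 3), sum) == co$geno$dosage))
  expect_true(all(co$geno$partitioned <= cnt))
})

test_that("marginal allele frequency matches the law of total expectation", {
  g <- c(0.2, 0.9)
  n <- 20000
  co <- simulate_psd_cohort(n, matrix(g, 2, 1), dirichlet = c(8, 2),
                            seed = 13, maf_min = 0)
  expected <- sum(g * colMeans(co$P))
  mc_se <- sqrt(expected * (1 - expected) / (2 * n))
  expect_lt(abs(mean(co$geno$dosage) / 2 - expected), 3 * mc_se)
})

test_that("conditional dosage variance at fixed P matches the closed form", {
  g <- c(0.2, 0.8)
  P <- c(0.5, 0.5)
  n <- 50000
  co <- simulate_psd_cohort(n, matrix(g, 2, 1), fixed = P, seed = 17,
                            maf_min = 0)
  v_theory <- var_att_marker(moments_fixed(P), g)  # 0.5 at these inputs
  v_emp <- var(co$geno$dosage[, 1])
  # MC SE of a variance: sqrt((mu4 - v^2)/n), bounded crudely
  expect_lt(abs(v_emp - v_theory), 3 * sqrt(2) * v_theory / sqrt(n))
})

test_that("cohort simulation is bit-reproducible under one run seed", {
  freqs <- matrix(runif(10, 0.3, 0.7), 2, 5)
  a <- simulate_psd_cohort(50, freqs, dirichlet = c(4, 1), seed = 23)
  b <- simulate_psd_cohort(50, freqs, dirichlet = c(4, 1), seed = 23)
  expect_identical(a$geno$hap, b$geno$hap)
  expect_identical(unclass(a$P), unclass(b$P))
})
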