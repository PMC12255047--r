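test_that("Balding-Nichols divergence has the expected cross-population spread", {
  m <- 10000
  f <- ancestral_freqs(rep(0.5, m), fst = 0.1, panel_size = 2000, seed = 3)
  # E[(f1 - f2)^2] = 2 F p (1-p) = 0.05
  d2 <- (f[1, ] - f[2, ])^2
  expect_lt(abs(mean(d2) - 0.05), 3 * sd(d2) / sqrt(m))
  # clipping away from the boundaries
  expect_true(all(f >= 1 / 4000) && all(f <= 1 - 1 / 4000))
  # no-drift limit
  f0 <- ancestral_freqs(rep(0.5, 200), fst = 1e-5, seed = 4)
  expect_lt(max(abs(f0 - 0.5)), 0.02)
  expect_error(ancestral_freqs(0.5, fst = 0), "strictly")
  expect_error(ancestral_freqs(1.2, fst = 0.1), "\\(0,1\\)")
})

test_that("panel LD decays with distance and matches the orthant oracle", {
  # two loci with latent correlation exp(-d/lambda) = 0.8
  lambda <- 0.01
  d <- -lambda * log(0.8)
  map <- genetic_map(c(0, 1000), c(0, d))
  pan <- simulate_panel(c(0.5, 0.5), map, lambda, n_hap = 1e5, seed = 5)
  r <- cor(pan$hap[, 1], pan$hap[, 2])
  expect_lt(abs(r - (2 / pi) * asin(0.8)), 3 / sqrt(1e5) + 0.005)

  # lambda -> 0: loci essentially independent
  pan0 <- simulate_panel(rep(0.5, 5), constant_map(5, 1e6, 1e-8), 1e-6,
                         n_hap = 2e4, seed = 6)
  cc <- cor(pan0$hap)
  expect_lt(max(abs(cc[upper.tri(cc)])), 4 / sqrt(2e4))

  # monotone decay along a longer map
  pan2 <- simulate_panel(rep(0.5, 30), constant_map(30, 3e6, 1e-8), 0.005,
                         n_hap = 2e4, seed = 7)
  r1 <- cor(pan2$hap[, 1], pan2$hap[, 2])
  r10 <- cor(pan2$hap[, 1], pan2$hap[, 15])
  r29 <- cor(pan2$hap[, 1], pan2$hap[, 30])
  expect_gt(r1, r10)
  expect_gt(r10, r29 - 0.01)

  expect_error(genetic_map(c(0, 10, 5), c(0, 1e-4, 2e-4)), "increasing")
})

test_that("founding pulse draws whole panel haplotypes at rate pi", {
  sc <- small_scenario(seed = 21, n_loci = 50, n_hap = 100, arms = character(0))
  pop <- found_admixed(sc$panels, 5000, pi = c(0.8, 0.2), seed = 8)
  frac1 <- mean(pop$anc[, 1] == 1)
  expect_lt(abs(frac1 - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  # constant ancestry per founder haplotype: exactly one segment
  expect_true(all(apply(pop$anc, 1, function(a) length(unique(a))) == 1))
  # every haplotype is an exact panel row
  h <- pop$hap[1, ]
  src <- sc$panels[[pop$anc[1, 1]]]$hap
  expect_true(any(colSums(t(src) != h) == 0))

  pop1 <- found_admixed(sc$panels, 100, pi = c(1, 0), seed = 9)
  expect_true(all(pop1$anc == 1L))
})

test_that("Wright-Fisher evolution conserves alleles and is identity at g=0", {
  sc <- small_scenario(seed = 22, n_loci = 80, n_hap = 60,
                       arms = character(0))
  pop <- found_admixed(sc$panels, 100, seed = 10)
  expect_identical(evolve_wright_fisher(pop, 0), pop)
  ev <- evolve_wright_fisher(pop, 5, seed = 11)
  expect_equal(ev$generations, 5L)
  # no mutation: per locus, allele values are a subset of the founder set
  for (k in c(1, 40, 80)) {
    expect_true(all(ev$hap[, k] %in% pop$hap[, k]))
  }
  expect_true(all(ev$anc %in% 1:2))
  expect_error(evolve_wright_fisher(pop, -1), "non-negative")
})

test_that("local-ancestry autocovariance decays like the single pulse", {
  sc <- small_scenario(seed = 23, n_loci = 200, n_hap = 200,
                       length_bp = 5e7, arms = character(0))
  pop <- found_admixed(sc$panels, 1500, pi = c(0.8, 0.2), seed = 12)
  ev <- evolve_wright_fisher(pop, 12, seed = 13)
  gm <- ev$map$morgans
  a1 <- ev$anc == 1L
  for (d in c(0.01, 0.05, 0.2)) {
    k0 <- 1L
    k1 <- which.min(abs(gm - d))
    x <- a1[, k0]; z <- a1[, k1]
    emp <- mean(x * z) - mean(x) * mean(z)
    pred <- 0.8 * 0.2 * exp(-12 * (gm[k1] - gm[k0]))
    mc_se <- sd(x * z) / sqrt(length(x))
    # drift across 12 generations adds correlation between haplotypes, so
    # allow the MC band plus a small drift margin
    expect_lt(abs(emp - pred), 4 * mc_se + 0.02)
  }
})

test_that("mosaic copying has exponential copy segments and g=0 reduction", {
  sc <- small_scenario(seed = 24, n_loci = 100, n_hap = 100,
                       arms = character(0))
  m0 <- mosaic_copy(sc$panels, 50, g = 0, seed = 14)
  expect_identical(m0$flavor, "mosaic_copy")
  expect_true(all(vapply(m0$copy_breaks, length, 0L) == 0))

  # long region so boundary truncation is negligible
  long <- build_forward_scenario(
    list(n_loci = 400, length_bp = 5e8, n_hap_panel = 100, n_admixed = 150,
         lambda = 0.002), seed = 25, arms = "mosaic")
  seg <- segment_lengths(long$mosaic, type = "copy")
  interior <- seg$length_cM[!seg$censored]
  expect_lt(abs(mean(interior) - 100 / 12),
            3 * sd(interior) / sqrt(length(interior)) + 0.15)
})

test_that("segment boundaries fall at locus midpoints and founders span all", {
  pop <- make_pop(matrix(c(1L, 1L, 2L, 2L, 2L), 1), cm = c(0, 1, 2, 3, 4))
  seg <- segment_lengths(pop, type = "ancestry")
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$end_cM[1], 1.5)
  expect_equal(seg$length_cM, c(1.5, 2.5))
  expect_true(all(seg$censored))

  sc <- small_scenario(seed = 26, n_loci = 40, n_hap = 50,
                       arms = character(0))
  fo <- found_admixed(sc$panels, 30, seed = 15)
  sf <- segment_lengths(fo, type = "ancestry")
  expect_true(all(sf$length_cM == max(sf$end_cM)))
})

test_that("realized global ancestry is a proper simplex near pi", {
  sc <- small_scenario(seed = 27, n_loci = 150, n_hap = 150,
                       n_admixed = 400, arms = "mosaic")
  P <- realized_global_ancestry(sc$mosaic, 2)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_lt(abs(mean(P[, 1]) - 0.8), 0.03)
  expect_identical(attr(P, "source"), "realized")

  one <- make_pop(matrix(1L, 2, 5), cm = 0:4)
  expect_equal(unclass(realized_global_ancestry(one, 2))[1, ], c(1, 0))
})

test_that("cross-segment alleles are independent in mosaic cohorts", {
  # pairs far apart relative to 1/g are almost always on distinct segments
  sc <- build_forward_scenario(
    list(n_loci = 100, length_bp = 5e7, n_hap_panel = 200, n_admixed = 2000,
         lambda = 0.002), seed = 28, arms = "mosaic")
  dos <- admixed_dosages(sc$mosaic, 2)
  gm <- sc$map$morgans
  k2 <- which.min(abs(gm - 0.45))
  # partial correlation given local ancestry via the adjusted regression
  co <- la_adjusted_ld(dos$dosage[, 1], dos$partitioned[, , k2],
                       dos$l_counts[, , k2])
  expect_lt(abs(co$coef[1]), 3 * co$se[1] + 0.02)
})
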