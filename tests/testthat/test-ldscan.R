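test_that("the self pair recovers coefficients of exactly 1", {
  sc <- small_scenario(seed = 51, n_loci = 60, n_hap = 150, n_admixed = 250,
                       arms = "mosaic")
  dos <- admixed_dosages(sc$mosaic, 2)
  k <- 10
  co <- la_adjusted_ld(dos$dosage[, k], dos$partitioned[, , k],
                       dos$l_counts[, , k])
  expect_equal(co$coef, c(1, 1), tolerance = 1e-8)

  pd <- panel_dosages(sc$panels[[1]])
  expect_equal(panel_ld(pd$dosage[, k], pd$dosage[, k])$coef, 1,
               tolerance = 1e-12)
})

test_that("panel LD slope matches the haplotype-tally covariance", {
  map <- genetic_map(c(0, 1000), c(0, 0.001))
  pan <- simulate_panel(c(0.4, 0.6), map, lambda = 0.01, n_hap = 4e4,
                        seed = 52)
  # direct 2x2 haplotype tally
  f <- mean(pan$hap[, 1]); g <- mean(pan$hap[, 2])
  D <- mean(pan$hap[, 1] * pan$hap[, 2]) - f * g
  pd <- panel_dosages(pan)
  est <- panel_ld(pd$dosage[, 1], pd$dosage[, 2])
  expect_lt(abs(est$coef - D / (g * (1 - g))), 3 * est$se + 1e-3)

  # independent loci give a slope near zero
  pan0 <- simulate_panel(c(0.5, 0.5), map, lambda = 1e-7, n_hap = 2e4,
                         seed = 53)
  pd0 <- panel_dosages(pan0)
  est0 <- panel_ld(pd0$dosage[, 1], pd0$dosage[, 2])
  expect_lt(abs(est0$coef), 3 * est0$se + 1e-3)

  expect_true(is.na(panel_ld(pd0$dosage[, 1], rep(0, 1e4))$coef))
})

test_that("pair catalog enumerates, caps and reproduces deterministically", {
  map <- genetic_map(c(0, 100, 200), c(0, 5e-4, 1e-3))
  pc <- pair_catalog(map, 3)
  expect_equal(nrow(pc), 3L)  # 3 unordered pairs among 3 loci
  expect_true(all(pc$dist_cM >= 0))

  map2 <- constant_map(40, 4e6, 1e-8)
  a <- pair_catalog(map2, 2, max_pairs = 50, seed = 54)
  b <- pair_catalog(map2, 2, max_pairs = 50, seed = 54)
  expect_identical(a, b)
  expect_equal(nrow(a), 50L)
  full <- pair_catalog(map2, 100, max_pairs = Inf)
  expect_equal(nrow(full), choose(40, 2))
})

test_that("distance-binned concordance detects copies and sign flips", {
  pairs <- data.frame(j = 1:40, k = 2:41, dist_bp = 1:40 * 1000,
                      dist_cM = runif(40, 0, 2.9))
  x <- rnorm(40)
  pairs$adm_coef_1 <- x; pairs$panel_coef_1 <- x
  pairs$adm_coef_2 <- x; pairs$panel_coef_2 <- -x
  bins <- concordance_by_distance(pairs, bin_edges_cM = c(0, 1.5, 3),
                                  min_pairs = 5)
  expect_equal(bins$r[bins$ancestry == 1], rep(1, 2), tolerance = 1e-12)
  expect_equal(bins$r[bins$ancestry == 2], rep(-1, 2), tolerance = 1e-12)
  expect_false(any(bins$flagged))
})

test_that("mosaic cohorts are the extended-PSD positive control", {
  sc <- small_scenario(seed = 55, n_loci = 120, n_hap = 500,
                       n_admixed = 1500, lambda = 0.002, length_bp = 5e6,
                       arms = "mosaic")
  dos <- admixed_dosages(sc$mosaic, 2)
  pairs <- pair_catalog(sc$map, 0.5, max_pairs = 120, seed = 56)
  scanned <- ld_pair_scan(pairs, dos, sc$panels)
  for (l in 1:2) {
    pr <- scanned[[paste0("panel_coef_", l)]]
    ad <- scanned[[paste0("adm_coef_", l)]]
    se <- sqrt(scanned[[paste0("adm_se_", l)]]^2 +
                 scanned[[paste0("panel_se_", l)]]^2)
    strong <- which(abs(scanned[[paste0("pred_corr_", l)]]) > 0.2)
    ok <- is.finite(ad[strong]) & is.finite(pr[strong])
    frac <- mean(abs(ad[strong] - pr[strong])[ok] < 3 * se[strong][ok])
    expect_gte(frac, 0.9)
    # and the panel estimate tracks the predicted weight closely
    expect_gt(cor(pr[strong][ok],
                  scanned[[paste0("pred_weight_", l)]][strong][ok]), 0.9)
  }
})

test_that("LD / segment-length overlay conserves counts and scale separation", {
  sc <- small_scenario(seed = 57, n_loci = 150, n_hap = 300,
                       n_admixed = 400, lambda = 5e-4, length_bp = 5e7,
                       arms = "mosaic")
  dos <- admixed_dosages(sc$mosaic, 2)
  pairs <- pair_catalog(sc$map, 3, max_pairs = 150, seed = 58)
  scanned <- ld_pair_scan(pairs, dos, sc$panels)
  seg <- segment_lengths(sc$mosaic, type = "ancestry")
  ov <- ld_vs_segments(scanned, seg, ancestry = 1)
  expect_equal(sum(ov$hist_counts), sum(!seg$censored))
  # panel LD (lambda = 0.05 cM) is far shorter than 100/12 cM segments
  expect_lt(ov$overlap_index, 0.05)
})
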