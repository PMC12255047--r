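#' End-to-end simulation experiments
#'
#' Three experiments reproduce the package's headline analyses at desk
#' scale: `run_power_experiment()` checks the closed-form standard-error
#' and power-ordering predictions on single-locus PSD cohorts;
#' `run_concordance_experiment()` compares ancestry-specific marginal
#' effects from admixed cohorts with single-continental effects across a
#' polygenicity grid; `run_ld_experiment()` contrasts
#' local-ancestry-adjusted LD in forward Wright-Fisher and mosaic-copy
#' cohorts against panel LD. Each takes a config list (defaults are the
#' study conditions) and a run seed, and returns summary tables.
#'
#' @name experiments
NULL

default_power_config <- function() {
  list(n = 10000, n_markers = 200, dirichlet = c(16, 4), sigma = 1,
       alpha = 0.15, order_n = 4000, order_markers_per_delta = 125,
       delta_grid = c(0, 0.2, 0.4, 0.6),
       indep_reps = 1000, indep_n = 2000, indep_g = c(0.3, 0.7),
       indep_alpha = 0.3,
       null_reps = 2000, null_n = 2000, null_g = c(0.3, 0.7))
}

#' Power-theory experiment on PSD cohorts
#'
#' Four sub-analyses: (1) predicted vs empirical OLS standard errors over
#' null markers; (2) mean Wald-statistic ordering (per-ancestry <= combined
#' <= standard GWAS) over equal-effect causal markers across an
#' allele-frequency-difference grid; (3) independence and unbiasedness of
#' ancestry-specific estimates over replicate cohorts at a fixed causal
#' marker; (4) null calibration of all tests at nominal 0.05.
#'
#' @param config named list overriding `default_power_config()`.
#' @param seed run seed.
#' @return list(se_table, se_summary, ordering, ordering_summary,
#'   independence, unbiasedness, null_calibration, config).
#' @export
run_power_experiment <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(default_power_config(), config)
  ## --- (1) SE prediction accuracy -----------------------------------
  g <- with_stage_seed(seed, "power_freqs",
    matrix(stats::runif(2 * cfg$n_markers, 0.1, 0.9), nrow = 2))
  cohort <- simulate_psd_cohort(cfg$n, g, dirichlet = cfg$dirichlet,
                                seed = stage_seed(seed, "power_cohort"))
  y <- with_stage_seed(seed, "power_trait",
                       stats::rnorm(cfg$n, 0, cfg$sigma))
  covar <- ancestry_covariates(cohort$P)
  mom <- moments_empirical(cohort$P)
  rv <- resid_var_given_ancestry(y, cohort$P)
  keep <- which(!cohort$excluded)
  att <- att_scan(y, cohort$geno$dosage, covar, markers = keep)
  trac <- tractor_scan(y, cohort$geno$partitioned, la_counts(cohort$la),
                       covar, markers = keep)
  se_table <- do.call(rbind, lapply(seq_along(keep), function(i) {
    k <- keep[i]
    rbind(
      data.frame(marker = k, method = "att", empirical = att$se[i],
                 predicted = predicted_se("att", mom, g[, k], rv, cfg$n)),
      data.frame(marker = k, method = "tractor_1", empirical = trac$se_1[i],
                 predicted = predicted_se("tractor", mom, g[, k], rv, cfg$n,
                                          ancestry = 1)),
      data.frame(marker = k, method = "tractor_2", empirical = trac$se_2[i],
                 predicted = predicted_se("tractor", mom, g[, k], rv, cfg$n,
                                          ancestry = 2)))
  }))
  se_table <- se_table[is.finite(se_table$empirical), ]
  se_summary <- list(
    correlation = stats::cor(se_table$predicted, se_table$empirical),
    median_rel_error = stats::median(
      abs(se_table$empirical - se_table$predicted) / se_table$predicted))
  ## --- (2) Wald ordering across frequency differences ---------------
  ordering <- run_ordering_block(cfg, seed)
  ag <- stats::aggregate(
    ordering[c("chisq_att", "chisq_combined", "chisq_fe",
               "chisq_1", "chisq_2")],
    by = ordering["delta"], FUN = mean)
  ag$att_excess <- ag$chisq_att - ag$chisq_combined
  ## --- (3) independence + unbiasedness at a fixed marker ------------
  reps <- replicate_tractor(cfg$indep_reps, cfg$indep_n, cfg$indep_g,
                            cfg$indep_alpha, cfg$sigma, cfg$dirichlet, seed)
  indep <- independence_diagnostic(reps$beta_1, reps$beta_2)
  unbias <- data.frame(
    method = c("att", "tractor_1", "tractor_2"),
    mean_beta = c(mean(reps$beta_att), mean(reps$beta_1), mean(reps$beta_2)),
    se_mean = c(stats::sd(reps$beta_att), stats::sd(reps$beta_1),
                stats::sd(reps$beta_2)) / sqrt(nrow(reps)),
    alpha = cfg$indep_alpha)
  ## --- (4) null calibration -----------------------------------------
  null <- replicate_tractor(cfg$null_reps, cfg$null_n, cfg$null_g, 0,
                            cfg$sigma, cfg$dirichlet,
                            stage_seed(seed, "null_block"))
  calib <- data.frame(
    test = c("att", "tractor_combined", "fe"),
    type1 = c(mean(null$p_att < 0.05), mean(null$p_combined < 0.05),
              mean(null$p_fe < 0.05)),
    n_reps = cfg$null_reps)
  list(se_table = se_table, se_summary = se_summary, ordering = ordering,
       ordering_summary = ag, independence = indep, unbiasedness = unbias,
       null_calibration = calib, config = cfg)
}

#' @keywords internal
run_ordering_block <- function(cfg, seed) {
  rows <- list()
  for (d in seq_along(cfg$delta_grid)) {
    delta <- cfg$delta_grid[d]
    g <- c(0.5 + delta / 2, 0.5 - delta / 2)
    cohorts_seed <- stage_seed(seed, paste0("ordering_", d))
    for (r in seq_len(cfg$order_markers_per_delta)) {
      s <- cohorts_seed + r
      cohort <- simulate_psd_cohort(cfg$order_n, matrix(g, 2, 1),
                                    dirichlet = cfg$dirichlet, seed = s)
      y <- cfg$alpha * cohort$geno$dosage[, 1] +
        with_stage_seed(s, "trait", stats::rnorm(cfg$order_n, 0, cfg$sigma))
      covar <- ancestry_covariates(cohort$P)
      fa <- fit_att(y, cohort$geno$dosage[, 1], covar)
      ft <- suppressMessages(fit_tractor(y, cohort$geno$partitioned[, , 1],
                                         la_counts(cohort$la)[, , 1], covar))
      fe <- suppressMessages(fe_combine(ft$beta, ft$se))
      rows[[length(rows) + 1]] <- data.frame(
        delta = delta, chisq_att = fa$chisq,
        chisq_combined = ft$chisq_combined, chisq_fe = fe$chisq_fe,
        chisq_1 = ft$chisq[1], chisq_2 = ft$chisq[2])
    }
  }
  do.call(rbind, rows)
}

#' Replicate single-marker PSD cohorts and collect fits
#'
#' @param n_reps replicate cohorts; @param n individuals per cohort.
#' @param g two-ancestry marker frequencies; @param alpha causal effect;
#' @param sigma noise sd; @param dirichlet global-ancestry concentration.
#' @param seed run seed.
#' @return data.frame with per-replicate ATT and ancestry-specific
#'   estimates, SEs and p-values.
#' @export
replicate_tractor <- function(n_reps, n, g, alpha, sigma, dirichlet, seed) {
  rows <- vector("list", n_reps)
  base <- stage_seed(seed, "replicates")
  for (r in seq_len(n_reps)) {
    s <- (base + r) %% 2147483647
    cohort <- simulate_psd_cohort(n, matrix(g, 2, 1), dirichlet = dirichlet,
                                  seed = s, maf_min = 0)
    y <- alpha * cohort$geno$dosage[, 1] +
      with_stage_seed(s, "trait", stats::rnorm(n, 0, sigma))
    covar <- ancestry_covariates(cohort$P)
    fa <- fit_att(y, cohort$geno$dosage[, 1], covar)
    ft <- suppressMessages(fit_tractor(y, cohort$geno$partitioned[, , 1],
                                       la_counts(cohort$la)[, , 1], covar))
    fe <- suppressMessages(fe_combine(ft$beta, ft$se))
    rows[[r]] <- data.frame(
      beta_att = fa$beta, se_att = fa$se, p_att = fa$p,
      beta_1 = ft$beta[1], se_1 = ft$se[1],
      beta_2 = ft$beta[2], se_2 = ft$se[2],
      p_combined = ft$p_combined, p_fe = fe$p_fe, chisq_fe = fe$chisq_fe)
  }
  do.call(rbind, rows)
}

default_forward_config <- function() {
  list(n_loci = 2000, length_bp = 5e7, recomb_rate = 1e-8,
       n_hap_panel = 2000, n_admixed = 2000, n_founders = 300,
       fst = 0.15, lambda = 0.05, pi = c(0.8, 0.2), generations = 12)
}

#' Build the paired source panels and admixed cohorts of a scenario
#'
#' Panels share one locus grid and Balding-Nichols-diverged frequencies;
#' the Wright-Fisher arm founds a small admixed pool by a single pulse and
#' evolves it for `generations` rounds (the last round expands to the
#' output size), while the mosaic arm copies independent panel segments at
#' breakpoint rate `generations` per Morgan.
#'
#' @param cfg config list overriding `default_forward_config()`.
#' @param seed run seed.
#' @param arms which cohorts to build ("wf", "mosaic").
#' @return list(panels, map, wf, mosaic, config).
#' @export
build_forward_scenario <- function(cfg = list(), seed = 1,
                                   arms = c("wf", "mosaic")) {
  cfg <- utils::modifyList(default_forward_config(), cfg)
  map <- constant_map(cfg$n_loci, cfg$length_bp, cfg$recomb_rate)
  p_anc <- with_stage_seed(seed, "anc_freqs_base",
                           stats::runif(cfg$n_loci, 0.1, 0.9))
  freqs <- ancestral_freqs(p_anc, cfg$fst, n_pop = 2,
                           panel_size = cfg$n_hap_panel, seed = seed)
  panels <- list(
    simulate_panel(freqs[1, ], map, cfg$lambda, cfg$n_hap_panel,
                   pop = "pop1", seed = seed),
    simulate_panel(freqs[2, ], map, cfg$lambda, cfg$n_hap_panel,
                   pop = "pop2", seed = seed))
  out <- list(panels = panels, map = map, config = cfg)
  if ("wf" %in% arms) {
    founders <- found_admixed(panels, cfg$n_founders, cfg$pi, seed = seed)
    n_per_gen <- c(rep(cfg$n_founders, cfg$generations - 1), cfg$n_admixed)
    out$wf <- evolve_wright_fisher(founders, cfg$generations,
                                   n_out = n_per_gen, seed = seed)
  }
  if ("mosaic" %in% arms) {
    out$mosaic <- mosaic_copy(panels, cfg$n_admixed, cfg$pi,
                              g = cfg$generations,
                              seed = stage_seed(seed, "mosaic_arm"))
  }
  out
}

#' Marginal-effect concordance across a polygenicity grid
#'
#' For each polygenicity, draws trait architectures shared between the
#' admixed cohort and the single-continental panels (heritability 1), fits
#' the local-ancestry-aware regression on the admixed cohort and plain
#' marginal regressions on each panel-derived cohort, and reports the
#' correlation between ancestry-specific admixed and single-continental
#' effect estimates at all markers and at causal markers only. Markers are
#' compared per ancestry only where the panel of that ancestry is
#' polymorphic (within-ancestry MAF >= `panel_maf`): a single-continental
#' GWAS has no estimate at a marker monomorphic in its own population.
#' Replicate architectures are pooled at the marker level.
#'
#' @param config forward-scenario overrides plus `polygenicity_grid`,
#'   `reps_per_poly`, `effect_sd`, `panel_maf`.
#' @param seed run seed.
#' @param scenario optionally a pre-built [build_forward_scenario()] result
#'   (its "wf" arm is used).
#' @return list(summary, marker_tables, config); `summary` carries pooled
#'   (`r_all`, `r_causal`) and per-replicate Fisher-z averaged (`r_all_z`)
#'   correlations.
#' @export
run_concordance_experiment <- function(config = list(), seed = 1,
                                       scenario = NULL) {
  cfg <- utils::modifyList(
    c(default_forward_config(),
      list(polygenicity_grid = c(1e-3, 5e-3, 1e-2, 5e-2),
           reps_per_poly = c(10, 4, 3, 2), effect_sd = 1,
           panel_maf = 0.01, n_hap_panel = 3000, n_admixed = 3000)),
    config)
  if (is.null(scenario)) {
    scenario <- build_forward_scenario(cfg, seed, arms = "wf")
  }
  pop <- scenario$wf %||% scenario$mosaic
  dos <- admixed_dosages(pop, n_anc = 2)
  P <- realized_global_ancestry(pop, n_anc = 2)
  covar <- ancestry_covariates(P)
  pdos <- lapply(scenario$panels, panel_dosages)
  panel_freq <- vapply(scenario$panels, function(p) p$realized_freq,
                       numeric(ncol(dos$dosage)))
  m <- ncol(dos$dosage)
  pooled <- colMeans(dos$dosage) / 2
  excluded <- pmin(pooled, 1 - pooled) < 0.01
  summary_rows <- list()
  tables <- list()
  for (pi_idx in seq_along(cfg$polygenicity_grid)) {
    poly <- cfg$polygenicity_grid[pi_idx]
    n_rep <- cfg$reps_per_poly[min(pi_idx, length(cfg$reps_per_poly))]
    acc <- list()
    for (r in seq_len(n_rep)) {
      s <- stage_seed(seed, sprintf("arch_%g_%d", poly, r))
      arch <- tryCatch(
        suppressMessages(draw_architecture(m, poly, cfg$effect_sd, seed = s)),
        error = function(e) NULL)
      if (is.null(arch)) {
        message("replicate ", r, " at polygenicity ", poly,
                " drew no causal locus; skipped")
        next
      }
      y_adm <- simulate_trait(dos$dosage[, arch$causal, drop = FALSE],
                              arch, h2 = 1)$y
      if (stats::sd(y_adm) == 0) next
      trac <- tractor_scan(y_adm, dos$partitioned, dos$l_counts, covar,
                           excluded = excluded)
      tab <- data.frame(marker = trac$marker, causal = trac$marker %in%
                          arch$causal, rep = r, polygenicity = poly,
                        adm_beta_1 = trac$beta_1, adm_beta_2 = trac$beta_2)
      for (l in 1:2) {
        y_pan <- simulate_trait(
          pdos[[l]]$dosage[, arch$causal, drop = FALSE], arch, h2 = 1)$y
        pan <- att_scan(y_pan, pdos[[l]]$dosage, markers = trac$marker)
        b <- pan$beta
        pf <- panel_freq[trac$marker, l]
        b[pf < cfg$panel_maf | pf > 1 - cfg$panel_maf] <- NA_real_
        tab[[paste0("panel_beta_", l)]] <- b
      }
      acc[[r]] <- tab
    }
    tab <- do.call(rbind, acc)
    tables[[as.character(poly)]] <- tab
    for (l in 1:2) {
      a <- tab[[paste0("adm_beta_", l)]]
      p <- tab[[paste0("panel_beta_", l)]]
      ok <- is.finite(a) & is.finite(p)
      okc <- ok & tab$causal
      per_rep <- vapply(split(seq_len(nrow(tab)), tab$rep), function(idx) {
        sel <- idx[ok[idx]]
        if (length(sel) >= 10) stats::cor(a[sel], p[sel]) else NA_real_
      }, 0)
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        polygenicity = poly, ancestry = l,
        r_all = stats::cor(a[ok], p[ok]),
        r_all_z = tanh(mean(atanh(pmin(pmax(per_rep, -1 + 1e-12),
                                       1 - 1e-12)), na.rm = TRUE)),
        r_causal = if (sum(okc) >= 3) stats::cor(a[okc], p[okc]) else NA_real_,
        n_all = sum(ok), n_causal = sum(okc))
    }
  }
  list(summary = do.call(rbind, summary_rows), marker_tables = tables,
       config = cfg)
}

#' Local-ancestry-adjusted LD experiment
#'
#' Runs the pair scan on the Wright-Fisher and mosaic-copy arms of one
#' scenario, bins the admixed-vs-panel concordance by distance, and
#' overlays LD extent on the segment-length distribution.
#'
#' @param config forward-scenario overrides plus `max_distance_cM`,
#'   `max_pairs`, `bin_edges_cM`.
#' @param seed run seed.
#' @param scenario optional pre-built scenario with both arms.
#' @return list(pairs_wf, pairs_mosaic, bins_wf, bins_mosaic, overlay_wf,
#'   segments_wf, config).
#' @export
run_ld_experiment <- function(config = list(), seed = 1, scenario = NULL) {
  cfg <- utils::modifyList(
    c(default_forward_config(),
      list(max_distance_cM = 3, max_pairs = 2000,
           bin_edges_cM = c(0, 0.05, 0.1, 0.25, 0.5, 1, 2, 3),
           overlay_max_distance_cM = 15, overlay_max_pairs = 600)),
    config)
  if (is.null(scenario)) {
    scenario <- build_forward_scenario(cfg, seed, arms = c("wf", "mosaic"))
  }
  pairs <- pair_catalog(scenario$map, cfg$max_distance_cM, cfg$max_pairs,
                        seed = seed)
  out <- list(config = cfg)
  for (arm in c("wf", "mosaic")) {
    pop <- scenario[[arm]]
    if (is.null(pop)) next
    dos <- admixed_dosages(pop, n_anc = 2)
    scanned <- ld_pair_scan(pairs, dos, scenario$panels)
    out[[paste0("pairs_", arm)]] <- scanned
    out[[paste0("bins_", arm)]] <- concordance_by_distance(
      scanned, cfg$bin_edges_cM)
  }
  if (!is.null(scenario$wf)) {
    seg <- segment_lengths(scenario$wf, type = "ancestry")
    out$segments_wf <- seg
    # the overlay needs pairs beyond the typical segment length, so it gets
    # its own wider (subsampled) catalog
    far <- pair_catalog(scenario$map, cfg$overlay_max_distance_cM,
                        cfg$overlay_max_pairs,
                        seed = stage_seed(seed, "overlay_pairs"))
    far_scan <- ld_pair_scan(far, admixed_dosages(scenario$wf, n_anc = 2),
                             scenario$panels)
    out$overlay_wf <- lapply(1:2, function(l) {
      ld_vs_segments(far_scan, seg[is.na(seg$ancestry) |
                                     seg$ancestry == l, ], ancestry = l)
    })
  }
  out
}
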