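#' Closed-form PSD/ePSD predictions
#'
#' Everything the single-locus PSD admixture model implies about GWAS in
#' admixed cohorts: the variance of the (ancestry-centered) marker dosage,
#' the diagonal covariance of the ancestry-partitioned dosages, the
#' resulting standard errors and Wald-statistic limits with their power
#' ordering, the extended-PSD expressions for marginal and local-ancestry
#' coefficients under imperfect tagging, and the effective-sample-size
#' factor for ancestry-specific estimates.
#'
#' Only the first two moments of the global ancestry distribution enter any
#' formula, collected in a `psd_moments` object.
#'
#' @name theory
NULL

#' First and second moments of global ancestry
#'
#' @param EP vector E[P_l] (sums to 1).
#' @param EPP matrix E[P_l P_l'] consistent with a distribution on the
#'   simplex: non-negative, symmetric, rows summing to EP.
#' @return a `psd_moments` object.
#' @export
psd_moments <- function(EP, EPP) {
  EPP <- as.matrix(EPP)
  if (abs(sum(EP) - 1) > 1e-8) stop("E[P] must sum to 1")
  if (any(EPP < -1e-12)) stop("second moments must be non-negative")
  if (any(abs(rowSums(EPP) - EP) > 1e-8)) {
    stop("second moments inconsistent: rowSums(EPP) must equal EP")
  }
  structure(list(n_anc = length(EP), EP = EP, EPP = EPP),
            class = "psd_moments")
}

#' @rdname psd_moments
#' @param P fixed proportion vector (degenerate distribution).
#' @export
moments_fixed <- function(P) psd_moments(P, outer(P, P))

#' @rdname psd_moments
#' @param conc Dirichlet concentration vector.
#' @export
moments_dirichlet <- function(conc) {
  a0 <- sum(conc)
  EP <- conc / a0
  EPP <- outer(conc, conc) / (a0 * (a0 + 1))
  diag(EPP) <- conc * (conc + 1) / (a0 * (a0 + 1))
  psd_moments(EP, EPP)
}

#' @rdname psd_moments
#' @param Pmat realized proportion matrix (individuals x ancestries).
#' @export
moments_empirical <- function(Pmat) {
  Pmat <- as.matrix(Pmat)
  psd_moments(colMeans(Pmat), crossprod(Pmat) / nrow(Pmat))
}

#' Variance of the ancestry-centered total marker dosage
#'
#' E[Var(M_ik | P_i)] in the general n_L form
#' 2 sum_l g_l(1-g_l) E[P_l] + 2 sum_l g_l^2 (E[P_l] - E[P_l^2])
#' - 2 sum_{l != l'} g_l g_l' E[P_l P_l'],
#' which for two ancestries reduces to
#' 2 sum_l g_l(1-g_l) E[P_l] + 2 (g_1 - g_2)^2 E[P_1 P_2].
#'
#' @param moments a `psd_moments`.
#' @param g per-ancestry marker allele frequencies.
#' @return non-negative scalar.
#' @export
var_att_marker <- function(moments, g) {
  stopifnot(inherits(moments, "psd_moments"), length(g) == moments$n_anc)
  EP <- moments$EP; EPP <- moments$EPP
  het <- sum(g^2 * (EP - diag(EPP)))
  cross <- sum(outer(g, g) * EPP) - sum(g^2 * diag(EPP))
  v <- 2 * sum(g * (1 - g) * EP) + 2 * het - 2 * cross
  max(v, 0)
}

#' Covariance matrix of the centered ancestry-partitioned dosages
#'
#' diag(2 g_l (1 - g_l) E[P_l]): the off-diagonals are exactly zero, which
#' is why ancestry-specific estimates from one regression are independent.
#'
#' @inheritParams var_att_marker
#' @return n_L x n_L diagonal matrix.
#' @export
var_tractor_matrix <- function(moments, g) {
  stopifnot(inherits(moments, "psd_moments"), length(g) == moments$n_anc)
  diag(2 * g * (1 - g) * moments$EP, nrow = length(g))
}

#' Predicted OLS standard error of a marker coefficient
#'
#' SE = sqrt(resid_var / (n * v)) where v is the dosage variance of the
#' method: [var_att_marker()] for the standard GWAS, the l-th diagonal of
#' [var_tractor_matrix()] for the ancestry-specific estimate. The
#' proportionality constant of the theory is E[Var(Y | P)], estimated in
#' practice by [resid_var_given_ancestry()].
#'
#' @param method "att" or "tractor".
#' @param moments,g as in [var_att_marker()].
#' @param resid_var E[Var(Y | P)].
#' @param n sample size.
#' @param ancestry which ancestry (for "tractor").
#' @return standard error.
#' @export
predicted_se <- function(method = c("att", "tractor"), moments, g, resid_var,
                         n, ancestry = 1) {
  method <- match.arg(method)
  stopifnot(n > 0, resid_var >= 0)
  v <- switch(method,
    att = var_att_marker(moments, g),
    tractor = var_tractor_matrix(moments, g)[ancestry, ancestry])
  if (v <= 0) stop("monomorphic marker: zero dosage variance")
  sqrt(resid_var / (n * v))
}

#' Residual variance conditional on ancestry
#'
#' Estimates E[Var(Y | P)] as the residual mean square of the trait
#' regressed on the ancestry covariates alone, matching the conditioning of
#' the asymptotic theory.
#'
#' @param y trait vector.
#' @param P global-ancestry matrix (or NULL for the unconditional variance).
#' @return scalar variance.
#' @export
resid_var_given_ancestry <- function(y, P = NULL) {
  X <- cbind(1, ancestry_covariates(P))
  fit <- ols_fit(y, X)
  if (fit$degenerate) stats::var(y) else fit$sigma2
}

#' Large-sample Wald statistic limits and their ordering
#'
#' Under equal causal effects across ancestries, the per-ancestry,
#' combined, and standard-GWAS Wald statistics divided by n converge to
#' beta^2 v / resid_var with v the corresponding dosage variance. The
#' ordering per-ancestry <= combined <= ATT always holds, with the ATT
#' excess driven by 2 (g_1 - g_2)^2 E[P_1 P_2].
#'
#' @param beta common marginal effect.
#' @param moments,g,resid_var as above.
#' @return list(per_ancestry vector, combined, att), each T/n.
#' @export
expected_statistics <- function(beta, moments, g, resid_var) {
  v_l <- diag(var_tractor_matrix(moments, g))
  list(per_ancestry = beta^2 * v_l / resid_var,
       combined = beta^2 * sum(v_l) / resid_var,
       att = beta^2 * var_att_marker(moments, g) / resid_var)
}

#' LD parameters between a marker and its linked causal variants
#'
#' @param f n_anc x n_causal causal allele frequencies f_lj.
#' @param g length-n_anc marker frequencies g_lk.
#' @param h n_anc x n_causal joint haplotype frequencies h_ljk
#'   (P(C = 1, M = 1)); must satisfy max(0, f+g-1) <= h <= min(f, g).
#' @return an `ld_params` object with the LD covariances D = h - f g.
#' @export
ld_params <- function(f, g, h) {
  f <- as.matrix(f); h <- as.matrix(h)
  stopifnot(length(g) == nrow(f), identical(dim(f), dim(h)))
  lo <- pmax(0, sweep(f, 1, g, `+`) - 1)
  hi <- pmin(f, matrix(g, nrow(f), ncol(f)))
  if (any(h < lo - 1e-12) || any(h > hi + 1e-12)) {
    stop("joint frequency outside Frechet bounds")
  }
  structure(list(f = f, g = g, h = h, D = h - sweep(f, 1, g, `*`)),
            class = "ld_params")
}

#' Ancestry-specific marginal effect under the extended PSD model
#'
#' beta_lk = sum_j D_ljk / (g_lk (1 - g_lk)) alpha_j: the effect a
#' single-continental GWAS of population l would estimate.
#'
#' @param ld an `ld_params`.
#' @param alpha causal effect vector.
#' @return per-ancestry coefficient vector.
#' @export
beta_tractor_epsd <- function(ld, alpha) {
  if (any(ld$g %in% c(0, 1))) stop("marker monomorphic in an ancestry")
  drop(ld$D %*% alpha) / (ld$g * (1 - ld$g))
}

#' Local-ancestry coefficients under the extended PSD model
#'
#' gamma_lk = sum_j ((f_lj - h_ljk)/(1 - g_lk) - (f_1j - h_1jk)/(1 - g_1k))
#' alpha_j for l >= 2; exactly zero under perfect tagging (f = h in every
#' ancestry), because the marker then leaves no residual causal signal for
#' local ancestry to absorb.
#'
#' @inheritParams beta_tractor_epsd
#' @return coefficient vector for ancestries 2..n_anc.
#' @export
gamma_tractor_epsd <- function(ld, alpha) {
  if (any(ld$g == 1)) stop("marker fixed in an ancestry")
  resid <- sweep(ld$f - ld$h, 1, 1 - ld$g, `/`)
  drop((resid[-1, , drop = FALSE] -
        matrix(resid[1, ], nrow(ld$f) - 1, ncol(ld$f), byrow = TRUE)) %*% alpha)
}

#' Single-pulse local-ancestry covariance between two loci
#'
#' Haplotype-level Cov(L^h_kl, L^h_jl' | P) under a Markov ancestry process
#' with switch rate `gens` per Morgan and stationary distribution P: the
#' multinomial covariance at distance zero, decaying as exp(-gens * d).
#' This is the package's single-pulse model for admixture LD; the paper's
#' framework leaves this covariance without a closed form.
#'
#' @param P ancestral proportion vector.
#' @param l,l2 ancestry indices.
#' @param d genetic distance in Morgans.
#' @param gens generations since admixture.
#' @return covariance.
#' @export
la_covariance_pulse <- function(P, l, l2, d, gens) {
  stopifnot(d >= 0, gens >= 0)
  base <- if (l == l2) P[l] * (1 - P[l]) else -P[l] * P[l2]
  base * exp(-gens * d)
}

#' Standard-GWAS marginal effect under the extended PSD model
#'
#' Combines the within-continental LD term (D weighted by mean ancestry)
#' and the admixture-LD term (allele-frequency products weighted by the
#' expected local-ancestry covariance) over the conditional-variance
#' denominator E[Var(M | P)]. With the single-pulse covariance at distance
#' 0 and the marker as its own sole causal variant this reduces to
#' beta = alpha.
#'
#' @param ld an `ld_params`.
#' @param alpha causal effects.
#' @param moments a `psd_moments`.
#' @param dist_M per-causal-variant genetic distance to the marker,
#'   Morgans.
#' @param gens generations since admixture.
#' @return scalar marginal effect.
#' @export
beta_att_epsd <- function(ld, alpha, moments, dist_M, gens) {
  L <- moments$n_anc
  EP <- moments$EP; EPP <- moments$EPP
  # E[Cov(L^h_kl, L^h_jl' | P)] under the pulse model
  ecov <- function(l, l2, d) {
    base <- if (l == l2) EP[l] - EPP[l, l] else -EPP[l, l2]
    base * exp(-gens * d)
  }
  num <- 0
  for (j in seq_along(alpha)) {
    within <- sum(ld$D[, j] * EP)
    admix <- 0
    for (l in seq_len(L)) for (l2 in seq_len(L)) {
      admix <- admix + ld$g[l] * ld$f[l2, j] * ecov(l, l2, dist_M[j])
    }
    num <- num + 2 * (within + admix) * alpha[j]
  }
  unname(num / var_att_marker(moments, ld$g))
}

#' Extended-PSD LD weight and correlation
#'
#' The weight D / (g (1-g)) is the coefficient the marker inherits per
#' causal variant; multiplying by sqrt(g(1-g) / (f(1-f))) converts it to
#' the LD correlation D / sqrt(g(1-g) f(1-f)).
#'
#' @param D LD covariance.
#' @param g marker frequency in (0,1).
#' @param f causal-variant frequency in (0,1).
#' @return numeric.
#' @export
epsd_ld_weight <- function(D, g) {
  if (any(g <= 0 | g >= 1)) stop("boundary marker frequency")
  D / (g * (1 - g))
}

#' @rdname epsd_ld_weight
#' @export
epsd_ld_corr <- function(D, g, f) {
  if (any(g <= 0 | g >= 1) || any(f <= 0 | f >= 1)) {
    stop("boundary allele frequency")
  }
  D / sqrt(g * (1 - g) * f * (1 - f))
}

#' Effective-sample-size factor for ancestry-specific estimates
#'
#' Relative to a single-continental GWAS of the same size, the
#' ancestry-specific standard error is inflated by 1/sqrt(E[P_l]), the
#' Z-score deflated by sqrt(E[P_l]), and the effective sample size is the
#' admixed sample size times sqrt(E[P_l]).
#'
#' @param mean_P E[P_l] in (0, 1].
#' @return list(se_inflation, z_deflation, n_multiplier).
#' @export
effective_n_factor <- function(mean_P) {
  if (any(mean_P <= 0) || any(mean_P > 1)) stop("E[P] must lie in (0, 1]")
  list(se_inflation = 1 / sqrt(mean_P),
       z_deflation = sqrt(mean_P),
       n_multiplier = sqrt(mean_P))
}
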