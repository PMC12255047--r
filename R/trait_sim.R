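#' Draw an additive trait architecture
#'
#' Each locus is independently causal with probability `polygenicity`;
#' causal effects are i.i.d. zero-mean normal on the raw allele dosage
#' scale and identical across ancestries. If no locus is drawn causal the
#' draw is repeated once before failing.
#'
#' @param n_loci loci on the grid.
#' @param polygenicity causal probability per locus, in (0, 1].
#' @param effect_sd standard deviation of causal effects (trait units per
#'   allele).
#' @param intercept trait intercept (default 0).
#' @param seed optional seed (stage "architecture").
#' @return a `trait_architecture`: list(causal, alpha, intercept,
#'   polygenicity).
#' @export
draw_architecture <- function(n_loci, polygenicity, effect_sd = 1,
                              intercept = 0, seed = NULL) {
  if (polygenicity <= 0 || polygenicity > 1) {
    stop("polygenicity must lie in (0, 1]")
  }
  with_stage_seed(seed, "architecture", {
    causal <- which(stats::runif(n_loci) < polygenicity)
    if (!length(causal)) {
      message("no causal locus drawn; resampling once")
      causal <- which(stats::runif(n_loci) < polygenicity)
      if (!length(causal)) stop("no causal locus drawn in two attempts")
    }
    structure(list(causal = causal,
                   alpha = stats::rnorm(length(causal), 0, effect_sd),
                   intercept = intercept, polygenicity = polygenicity),
              class = "trait_architecture")
  })
}

#' Simulate a quantitative trait from causal dosages
#'
#' Y_i = sum_j C_ij alpha_j + alpha_0 + eps_i. The environmental noise
#' variance is Var(genetic values) * (1 - h2) / h2, so the realized genetic
#' variance share is approximately h2; at h2 = 1 the noise is exactly zero.
#'
#' @param causal_dosages n x n_causal matrix of dosages at the causal loci
#'   (columns in the order of `arch$causal`).
#' @param arch a `trait_architecture`.
#' @param h2 heritability in (0, 1].
#' @param seed optional seed (stage "trait_noise").
#' @return list(y, genetic, eps).
#' @export
simulate_trait <- function(causal_dosages, arch, h2 = 1, seed = NULL) {
  causal_dosages <- as.matrix(causal_dosages)
  if (ncol(causal_dosages) != length(arch$causal)) {
    stop("dosage columns do not cover the causal set")
  }
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  genetic <- drop(causal_dosages %*% arch$alpha)
  var_g <- stats::var(genetic)
  if (h2 < 1) {
    if (var_g == 0) {
      stop("degenerate architecture: zero genetic variance with h2 < 1")
    }
    eps <- with_stage_seed(seed, "trait_noise",
      stats::rnorm(length(genetic), 0, sqrt(var_g * (1 - h2) / h2)))
  } else {
    eps <- rep(0, length(genetic))
  }
  list(y = genetic + arch$intercept + eps, genetic = genetic, eps = eps)
}
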