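#' Single-locus PSD cohort simulator
#'
#' Under the Pritchard-Stephens-Donnelly (PSD) admixture model a genotype is
#' generated in three layers: a per-individual global ancestry vector P_i on
#' the simplex, per-haplotype local ancestry labels drawn from P_i
#' independently at every locus, and alleles drawn Bernoulli from the
#' ancestry-specific allele frequency of the labelled source population.
#' Loci are mutually independent, which is what makes the closed-form power
#' algebra tractable.
#'
#' @name psd_sim
NULL

#' Draw global ancestry proportions
#'
#' @param n number of individuals.
#' @param fixed optional fixed proportion vector shared by all individuals
#'   (must sum to 1).
#' @param dirichlet optional Dirichlet concentration vector (all entries
#'   positive); exactly one of `fixed`/`dirichlet` must be given.
#' @param seed optional integer seed (stage "global_ancestry").
#' @return a `global_ancestry` matrix (n x n_ancestries), rows summing to 1,
#'   with a `source` attribute of "fixed" or "dirichlet".
#' @export
draw_global_ancestry <- function(n, fixed = NULL, dirichlet = NULL, seed = NULL) {
  stopifnot(n >= 1)
  if (is.null(fixed) == is.null(dirichlet)) {
    stop("supply exactly one of `fixed` or `dirichlet`")
  }
  if (!is.null(fixed)) {
    if (any(fixed < 0) || any(fixed > 1)) {
      stop("fixed proportions out of [0,1]: entry ",
           which(fixed < 0 | fixed > 1)[1])
    }
    if (abs(sum(fixed) - 1) > 1e-8) {
      stop("fixed proportions sum to ", sum(fixed), ", not 1")
    }
    P <- matrix(fixed / sum(fixed), nrow = n, ncol = length(fixed), byrow = TRUE)
    return(global_ancestry(P, source = "fixed"))
  }
  if (any(dirichlet <= 0)) {
    stop("dirichlet concentration must be positive: entry ",
         which(dirichlet <= 0)[1])
  }
  P <- with_stage_seed(seed, "global_ancestry", {
    G <- matrix(stats::rgamma(n * length(dirichlet), shape = rep(dirichlet, each = n)),
                nrow = n)
    G / rowSums(G)
  })
  global_ancestry(P, source = "dirichlet")
}

#' @keywords internal
global_ancestry <- function(P, source) {
  P <- as.matrix(P)
  stopifnot(all(P >= 0), all(P <= 1 + 1e-12),
            all(abs(rowSums(P) - 1) < 1e-12))
  structure(P, class = c("global_ancestry", "matrix"), source = source)
}

#' Draw local ancestry labels under the PSD model
#'
#' Every haplotype at every locus receives an independent categorical draw
#' from the individual's global ancestry, so the diploid per-locus counts are
#' Multinomial(2, P_i) and always sum to 2.
#'
#' @param P a `global_ancestry` matrix (or plain matrix with rows on the
#'   simplex).
#' @param n_loci number of independent loci.
#' @param seed optional integer seed (stage "local_ancestry").
#' @return a `local_ancestry` object: list with `hap`, an
#'   n x 2 x n_loci integer array of ancestry indices (1-based), and `n_anc`.
#' @export
draw_local_ancestry <- function(P, n_loci, seed = NULL) {
  if (n_loci <= 0) stop("n_loci must be positive")
  P <- as.matrix(P)
  n <- nrow(P); L <- ncol(P)
  labs <- with_stage_seed(seed, "local_ancestry", {
    u <- matrix(stats::runif(n * 2 * n_loci), nrow = n)
    cum <- P[, 1]
    lab <- matrix(1L, nrow = n, ncol = 2 * n_loci)
    if (L > 1) {
      for (l in seq_len(L - 1)) {
        # vector recycles down rows: row i compared against cum[i]
        lab <- lab + (u > cum)
        if (l < L - 1) cum <- cum + P[, l + 1]
      }
    }
    lab
  })
  structure(list(hap = array(labs, dim = c(n, 2, n_loci)), n_anc = L),
            class = "local_ancestry")
}

#' Diploid local ancestry counts L_ikl
#'
#' @param la a `local_ancestry` object.
#' @return integer array n x n_ancestries x n_loci; per individual and locus
#'   the counts sum to 2.
#' @export
la_counts <- function(la) {
  n <- dim(la$hap)[1]; m <- dim(la$hap)[3]; L <- la$n_anc
  cnt <- array(0L, dim = c(n, L, m))
  for (l in seq_len(L)) {
    cnt[, l, ] <- (la$hap[, 1, ] == l) + (la$hap[, 2, ] == l)
  }
  cnt
}

#' Build an ancestry-by-locus allele frequency table
#'
#' @param freqs matrix n_ancestries x n_loci of reference allele frequencies.
#' @return `freq_table` matrix with a `monomorphic` attribute flagging loci
#'   fixed (0 or 1) in every ancestry; such loci are unusable for
#'   association.
#' @export
freq_table <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (any(freqs < 0) || any(freqs > 1)) stop("allele frequencies out of [0,1]")
  mono <- apply(freqs, 2, function(f) all(f == 0) || all(f == 1))
  structure(freqs, class = c("freq_table", "matrix"), monomorphic = mono)
}

#' Draw phased genotypes given local ancestry
#'
#' Alleles are Bernoulli(f_{l,k}) for the labelled ancestry l, independent
#' across haplotypes (source-population HWE) and across loci.
#'
#' @param la a `local_ancestry` object.
#' @param freqs matrix n_ancestries x n_loci of allele frequencies
#'   (see [freq_table()]).
#' @param seed optional integer seed (stage "alleles").
#' @return a `genotype_set`: list with `hap` (n x 2 x n_loci 0/1 array) and
#'   `dosage` (n x n_loci, values 0/1/2).
#' @export
draw_genotypes <- function(la, freqs, seed = NULL) {
  freqs <- as.matrix(freqs)
  n <- dim(la$hap)[1]; m <- dim(la$hap)[3]
  if (ncol(freqs) != m) stop("freqs has ", ncol(freqs), " loci, expected ", m)
  if (max(la$hap) > nrow(freqs)) {
    stop("ancestry index ", max(la$hap), " has no frequency row")
  }
  G <- with_stage_seed(seed, "alleles", {
    locus_of <- rep(seq_len(m), each = n * 2)
    p <- freqs[cbind(as.vector(la$hap), locus_of)]
    array(stats::rbinom(n * 2 * m, 1L, p), dim = c(n, 2, m))
  })
  dosage <- matrix(G[, 1, ], n, m) + matrix(G[, 2, ], n, m)
  structure(list(hap = G, dosage = dosage), class = "genotype_set")
}

#' Partition diploid dosage by local ancestry
#'
#' Computes M_ikl, the reference allele count at locus k carried on
#' chromosome copies of ancestry l. By construction
#' sum_l M_ikl = M_ik and M_ikl <= L_ikl.
#'
#' @param geno a `genotype_set`.
#' @param la the matching `local_ancestry`.
#' @return the `genotype_set` with an added `partitioned` element,
#'   an n x n_ancestries x n_loci array.
#' @export
partition_dosage <- function(geno, la) {
  if (!identical(dim(geno$hap), dim(la$hap))) {
    stop("genotype and local-ancestry arrays differ in shape")
  }
  n <- dim(geno$hap)[1]; m <- dim(geno$hap)[3]; L <- la$n_anc
  part <- array(0L, dim = c(n, L, m))
  for (l in seq_len(L)) {
    part[, l, ] <- (la$hap[, 1, ] == l) * geno$hap[, 1, ] +
                   (la$hap[, 2, ] == l) * geno$hap[, 2, ]
  }
  geno$partitioned <- part
  geno
}

#' Simulate a complete PSD cohort
#'
#' Convenience wrapper chaining ancestry, local ancestry, alleles and dosage
#' partitioning with per-stage substreams of one run seed.
#'
#' @param n individuals; @param freqs ancestry x locus frequency matrix.
#' @param fixed,dirichlet global-ancestry specification, see
#'   [draw_global_ancestry()].
#' @param seed run seed.
#' @param maf_min loci with pooled cohort MAF below this are flagged
#'   `excluded` (default 0.01) to avoid degenerate OLS designs.
#' @return list with `P`, `la`, `geno` (partitioned), `freqs`, `excluded`.
#' @export
simulate_psd_cohort <- function(n, freqs, fixed = NULL, dirichlet = NULL,
                                seed = NULL, maf_min = 0.01) {
  freqs <- as.matrix(freqs)
  P <- draw_global_ancestry(n, fixed = fixed, dirichlet = dirichlet, seed = seed)
  la <- draw_local_ancestry(P, ncol(freqs), seed = seed)
  geno <- draw_genotypes(la, freqs, seed = seed)
  geno <- partition_dosage(geno, la)
  pooled <- colMeans(geno$dosage) / 2
  excluded <- pmin(pooled, 1 - pooled) < maf_min
  list(P = P, la = la, geno = geno, freqs = freqs, excluded = excluded)
}
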