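# Small programmatic fixtures shared across tests.

# Local-ancestry object with given label array (n x 2 x m).
make_la <- function(labels, n_anc = 2) {
  structure(list(hap = labels, n_anc = n_anc), class = "local_ancestry")
}

# Genotype set from an explicit haplotype array.
make_geno <- function(hap) {
  n <- dim(hap)[1]; m <- dim(hap)[3]
  dosage <- matrix(hap[, 1, ], n, m) + matrix(hap[, 2, ], n, m)
  structure(list(hap = hap, dosage = dosage), class = "genotype_set")
}

# Admixed-population stub with an explicit ancestry track on a cM grid.
make_pop <- function(anc, cm, hap = NULL, copy_breaks = NULL) {
  m <- ncol(anc)
  map <- admixld::genetic_map(seq(0, by = 1000, length.out = m),
                              cm / 100)
  structure(list(hap = hap %||% matrix(0L, nrow(anc), m), anc = anc,
                 map = map, n_ind = nrow(anc) %/% 2L, flavor = "stub",
                 generations = NA, pi = NA, copy_breaks = copy_breaks),
            class = "admixed_population")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-panel scenario reused by LD tests (tight LD, short region).
small_scenario <- function(seed = 11, n_loci = 200, n_hap = 400,
                           n_admixed = 300, lambda = 0.002,
                           length_bp = 5e6, arms = c("wf", "mosaic")) {
  admixld::build_forward_scenario(
    list(n_loci = n_loci, length_bp = length_bp, n_hap_panel = n_hap,
         n_admixed = n_admixed, n_founders = 150, lambda = lambda),
    seed = seed, arms = arms)
}
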