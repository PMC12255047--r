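#' Forward-time admixture simulators with exact local-ancestry tracking
#'
#' Two ways to build an admixed cohort from source haplotype panels:
#' `evolve_wright_fisher()` founds a population by a single admixture pulse
#' and evolves it forward as a Wright-Fisher population with recombination,
#' inheriting alleles and ancestry labels jointly (realistic; the extended
#' PSD assumption can fail); `mosaic_copy()` pastes together independently
#' re-drawn panel haplotypes segment by segment (the extended PSD model holds
#' by construction, which makes it the positive control).
#'
#' Coordinates are 0-based base pairs; genetic distance is Morgans
#' internally and centiMorgans at reporting interfaces.
#'
#' @name admix_forward
NULL

#' Genetic map on a constant recombination rate
#'
#' @param n_loci number of loci, evenly spaced.
#' @param length_bp region length in base pairs.
#' @param rate recombination rate per bp per generation (default 1e-8).
#' @return a `genetic_map`: list of strictly increasing `bp` (0-based) and
#'   `morgans` (0 at the first locus).
#' @export
constant_map <- function(n_loci, length_bp, rate = 1e-8) {
  stopifnot(n_loci >= 2, length_bp > 0, rate > 0)
  bp <- round(seq(0, length_bp - 1, length.out = n_loci))
  genetic_map(bp, (bp - bp[1]) * rate)
}

#' @rdname constant_map
#' @param bp,morgans explicit position vectors.
#' @export
genetic_map <- function(bp, morgans) {
  if (any(diff(bp) <= 0) || any(diff(morgans) <= 0)) {
    stop("map positions must be strictly increasing")
  }
  if (morgans[1] != 0) stop("genetic position must be 0 at the first locus")
  structure(list(bp = as.numeric(bp), morgans = as.numeric(morgans)),
            class = "genetic_map")
}

#' Balding-Nichols divergence of population allele frequencies
#'
#' Per-population frequencies are drawn Beta(p(1-F)/F, (1-p)(1-F)/F) around
#' the ancestral frequency p, so that E[freq] = p and the expected squared
#' difference between two populations at a locus is 2 F p (1-p). Output is
#' clipped away from the boundaries by 1/(2 * panel_size).
#'
#' @param p_anc ancestral frequency vector (one per locus), in (0,1).
#' @param fst drift parameter per population, 0 < F < 1 (scalar recycled).
#' @param n_pop number of descendant populations (default 2).
#' @param panel_size haplotypes per panel, sets the boundary clip.
#' @param seed optional seed (stage "ancestral_freqs").
#' @return `freq_table` matrix n_pop x n_loci.
#' @export
ancestral_freqs <- function(p_anc, fst, n_pop = 2, panel_size = 2000,
                            seed = NULL) {
  if (any(p_anc <= 0) || any(p_anc >= 1)) stop("p_anc must lie in (0,1)")
  fst <- rep(fst, length.out = n_pop)
  if (any(fst <= 0) || any(fst >= 1)) stop("Fst must lie strictly in (0,1)")
  m <- length(p_anc)
  clip <- 1 / (2 * panel_size)
  f <- with_stage_seed(seed, "ancestral_freqs", {
    out <- matrix(0, n_pop, m)
    for (l in seq_len(n_pop)) {
      s <- (1 - fst[l]) / fst[l]
      out[l, ] <- stats::rbeta(m, p_anc * s, (1 - p_anc) * s)
    }
    out
  })
  freq_table(pmin(pmax(f, clip), 1 - clip))
}

#' Simulate a source haplotype panel with distance-decaying LD
#'
#' Latent-Gaussian haplotype model: each haplotype is a stationary AR(1)
#' Gaussian sequence along the map with inter-locus correlation
#' exp(-d / lambda) for genetic distance d Morgans, thresholded at the
#' (1 - f_k)-quantile so the marginal allele frequency at locus k is f_k.
#' Pairwise allele correlation decreases monotonically with distance and is
#' computable from the bivariate-normal orthant probability.
#'
#' @param freq per-locus allele frequency vector for this population.
#' @param map a `genetic_map` over the same loci.
#' @param lambda LD decay length in Morgans (> 0).
#' @param n_hap number of haplotypes.
#' @param pop population label.
#' @param seed optional seed (stage "panel_<pop>").
#' @return a `haplotype_panel`: list(pop, hap, freq, realized_freq, map,
#'   lambda).
#' @export
simulate_panel <- function(freq, map, lambda, n_hap, pop = "pop1", seed = NULL) {
  stopifnot(lambda > 0, n_hap >= 2)
  m <- length(map$morgans)
  if (length(freq) != m) stop("freq and map cover different loci")
  rho <- exp(-diff(map$morgans) / lambda)
  hap <- with_stage_seed(seed, paste0("panel_", pop), {
    Z <- matrix(0, n_hap, m)
    Z[, 1] <- stats::rnorm(n_hap)
    for (k in seq_len(m - 1)) {
      Z[, k + 1] <- rho[k] * Z[, k] +
        sqrt(1 - rho[k]^2) * stats::rnorm(n_hap)
    }
    thr <- stats::qnorm(1 - freq)
    matrix(as.integer(sweep(Z, 2, thr, `>`)), n_hap, m)
  })
  structure(list(pop = pop, hap = hap, freq = freq,
                 realized_freq = colMeans(hap), map = map, lambda = lambda),
            class = "haplotype_panel")
}

#' Found an admixed population by a single pulse
#'
#' Each founder haplotype takes an ancestry from `pi` and is copied whole
#' from a uniformly chosen haplotype of the matching panel, so founder
#' local-ancestry tracks have exactly one segment.
#'
#' @param panels list of `haplotype_panel`s on one locus grid.
#' @param n_ind admixed individuals to create.
#' @param pi admixture proportions (sums to 1), default c(0.8, 0.2).
#' @param seed optional seed (stage "founding").
#' @return an `admixed_population`: list(hap, anc, map, n_ind, flavor,
#'   generations, pi, copy_breaks).
#' @export
found_admixed <- function(panels, n_ind, pi = c(0.8, 0.2), seed = NULL) {
  stopifnot(length(panels) >= 2, abs(sum(pi) - 1) < 1e-8)
  if (any(vapply(panels, function(p) nrow(p$hap), 0L) < 1)) {
    stop("empty haplotype panel")
  }
  map <- panels[[1]]$map
  m <- length(map$morgans)
  nh <- 2L * n_ind
  out <- with_stage_seed(seed, "founding", {
    anc_of_hap <- sample.int(length(panels), nh, replace = TRUE, prob = pi)
    hap <- matrix(0L, nh, m)
    for (h in seq_len(nh)) {
      src <- panels[[anc_of_hap[h]]]
      hap[h, ] <- src$hap[sample.int(nrow(src$hap), 1L), ]
    }
    list(hap = hap,
         anc = matrix(anc_of_hap, nh, m),
         breaks = rep(list(numeric(0)), nh))
  })
  structure(list(hap = out$hap, anc = out$anc, map = map, n_ind = n_ind,
                 flavor = "founder", generations = 0L, pi = pi,
                 copy_breaks = out$breaks),
            class = "admixed_population")
}

#' Evolve an admixed population by Wright-Fisher reproduction
#'
#' Each generation replaces the population with `n_out` offspring (defaults
#' to the current size). Every offspring draws two distinct parents
#' uniformly; each transmitted gamete recombines the parent's haplotypes
#' with breakpoints from a Poisson process of rate 1 per Morgan and a fair
#' choice of starting haplotype. Alleles and ancestry labels are inherited
#' jointly, so the local-ancestry track stays exact and every allele remains
#' traceable to a founder panel haplotype (no mutation).
#'
#' @param pop an `admixed_population` with at least 2 individuals.
#' @param generations non-negative number of rounds.
#' @param n_out population size per round (scalar or vector per round).
#' @param seed optional seed (stage "mating").
#' @return the evolved `admixed_population` (flavor "forward_wf").
#' @export
evolve_wright_fisher <- function(pop, generations, n_out = NULL, seed = NULL) {
  if (generations < 0) stop("generations must be non-negative")
  if (pop$n_ind < 2) stop("need at least 2 individuals")
  if (generations == 0) return(pop)
  n_out <- rep(if (is.null(n_out)) pop$n_ind else n_out,
               length.out = generations)
  gmap <- pop$map$morgans
  total <- gmap[length(gmap)]
  with_stage_seed(seed, "mating", {
    for (gen in seq_len(generations)) {
      N <- n_out[gen]
      new_hap <- matrix(0L, 2L * N, length(gmap))
      new_anc <- matrix(0L, 2L * N, length(gmap))
      for (i in seq_len(N)) {
        par <- sample.int(pop$n_ind, 2L)
        for (w in 1:2) {
          g <- gamete_from(pop, par[w], gmap, total)
          new_hap[2L * i - 2L + w, ] <- g$hap
          new_anc[2L * i - 2L + w, ] <- g$anc
        }
      }
      pop$hap <- new_hap
      pop$anc <- new_anc
      pop$n_ind <- N
      pop$generations <- pop$generations + 1L
      pop$copy_breaks <- NULL
    }
    pop$flavor <- "forward_wf"
    pop
  })
}

#' @keywords internal
gamete_from <- function(pop, parent, gmap, total) {
  r1 <- 2L * parent - 1L
  nb <- stats::rpois(1L, total)
  start <- sample.int(2L, 1L)
  if (nb == 0L) {
    row <- r1 + start - 1L
    return(list(hap = pop$hap[row, ], anc = pop$anc[row, ]))
  }
  bks <- sort(stats::runif(nb, 0, total))
  use2 <- ((start - 1L + findInterval(gmap, bks)) %% 2L) == 1L
  hap <- pop$hap[r1, ]
  anc <- pop$anc[r1, ]
  hap[use2] <- pop$hap[r1 + 1L, use2]
  anc[use2] <- pop$anc[r1 + 1L, use2]
  list(hap = hap, anc = anc)
}

#' Build an admixed cohort by independent mosaic copying
#'
#' Ancestry breakpoints are a Poisson process of rate `g` per Morgan;
#' segment ancestries are i.i.d. from `pi`; every segment is copied from an
#' independently re-chosen panel haplotype of that ancestry. Conditional on
#' local ancestry, alleles on different segments are therefore independent
#' and within-segment LD equals panel LD: the extended PSD model holds by
#' construction.
#'
#' @inheritParams found_admixed
#' @param g generations since admixture (breakpoint rate per Morgan).
#' @return an `admixed_population` (flavor "mosaic_copy") whose
#'   `copy_breaks` element stores the latent per-haplotype breakpoints in
#'   Morgans.
#' @export
mosaic_copy <- function(panels, n_ind, pi = c(0.8, 0.2), g = 12, seed = NULL) {
  stopifnot(length(panels) >= 2, abs(sum(pi) - 1) < 1e-8, g >= 0)
  if (g == 0) {
    pop <- found_admixed(panels, n_ind, pi, seed = seed)
    pop$flavor <- "mosaic_copy"
    return(pop)
  }
  map <- panels[[1]]$map
  gmap <- map$morgans
  total <- gmap[length(gmap)]
  m <- length(gmap)
  nh <- 2L * n_ind
  out <- with_stage_seed(seed, "mosaic", {
    hap <- matrix(0L, nh, m)
    anc <- matrix(0L, nh, m)
    breaks <- vector("list", nh)
    for (h in seq_len(nh)) {
      nb <- stats::rpois(1L, g * total)
      bks <- sort(stats::runif(nb, 0, total))
      seg <- findInterval(gmap, bks) + 1L
      seg_anc <- sample.int(length(panels), nb + 1L, replace = TRUE, prob = pi)
      for (s in seq_len(nb + 1L)) {
        idx <- which(seg == s)
        if (!length(idx)) next
        src <- panels[[seg_anc[s]]]
        hap[h, idx] <- src$hap[sample.int(nrow(src$hap), 1L), idx]
        anc[h, idx] <- seg_anc[s]
      }
      breaks[[h]] <- bks
    }
    list(hap = hap, anc = anc, breaks = breaks)
  })
  structure(list(hap = out$hap, anc = out$anc, map = map, n_ind = n_ind,
                 flavor = "mosaic_copy", generations = g, pi = pi,
                 copy_breaks = out$breaks),
            class = "admixed_population")
}

#' Local-ancestry / copy segment lengths
#'
#' For `type = "ancestry"` (default) segments are per-haplotype maximal runs
#' of constant ancestry label along the locus grid, with boundaries at
#' midpoints between the flanking loci. For `type = "copy"` (mosaic cohorts
#' only) the latent copying breakpoints are used directly, so segment
#' lengths follow the Exponential(mean 100/g cM) of the breakpoint process
#' regardless of whether neighbouring segments share an ancestry label.
#' Segments censored by the region boundary are flagged and excluded from
#' summaries by default.
#'
#' @param pop an `admixed_population`.
#' @param type "ancestry" or "copy".
#' @return data.frame with hap, ancestry (NA for copy segments),
#'   start_cM, end_cM, length_cM, censored.
#' @export
segment_lengths <- function(pop, type = c("ancestry", "copy")) {
  type <- match.arg(type)
  cm <- pop$map$morgans * 100
  total <- cm[length(cm)]
  if (type == "copy") {
    if (is.null(pop$copy_breaks)) {
      stop("copy breakpoints are only tracked for mosaic cohorts")
    }
    segs <- lapply(seq_along(pop$copy_breaks), function(h) {
      e <- c(pop$copy_breaks[[h]] * 100, total)
      s <- c(0, e[-length(e)])
      data.frame(hap = h, ancestry = NA_integer_, start_cM = s, end_cM = e,
                 length_cM = e - s,
                 censored = seq_along(e) %in% c(1L, length(e)))
    })
    return(do.call(rbind, segs))
  }
  segs <- lapply(seq_len(nrow(pop$anc)), function(h) {
    r <- rle(pop$anc[h, ])
    ends_idx <- cumsum(r$lengths)
    starts_idx <- c(1L, ends_idx[-length(ends_idx)] + 1L)
    # run boundaries at midpoints between flanking loci
    bnd <- if (length(ends_idx) > 1) {
      (cm[ends_idx[-length(ends_idx)]] + cm[starts_idx[-1]]) / 2
    } else numeric(0)
    s <- c(0, bnd); e <- c(bnd, total)
    data.frame(hap = h, ancestry = r$values, start_cM = s, end_cM = e,
               length_cM = e - s,
               censored = seq_along(s) %in% c(1L, length(s)))
  })
  do.call(rbind, segs)
}

#' Realized (Morgan-weighted) global ancestry of an admixed cohort
#'
#' The fraction of each individual's diploid genetic length carried on
#' segments of each ancestry; depends only on genetic positions, not on the
#' bp scale.
#'
#' @param pop an `admixed_population`.
#' @param n_anc number of ancestries (default: max label present).
#' @return a `global_ancestry` matrix (source "realized").
#' @export
realized_global_ancestry <- function(pop, n_anc = NULL) {
  gm <- pop$map$morgans
  m <- length(gm)
  # trapezoid locus weights: half-interval at each side
  w <- (c(diff(gm), 0) + c(0, diff(gm))) / 2
  w <- w / sum(w)
  L <- n_anc %||% max(pop$anc)
  P <- matrix(0, pop$n_ind, L)
  for (l in seq_len(L)) {
    frac <- (pop$anc == l) %*% w
    P[, l] <- (frac[seq(1, 2 * pop$n_ind, 2)] + frac[seq(2, 2 * pop$n_ind, 2)]) / 2
  }
  global_ancestry(P, source = "realized")
}

#' Diploid dosage views of an admixed cohort
#'
#' Pairs consecutive haplotype rows into individuals and returns total,
#' ancestry-partitioned dosages and diploid local-ancestry counts.
#'
#' @param pop an `admixed_population`.
#' @param n_anc number of ancestries.
#' @return list(dosage n x m, partitioned n x L x m, l_counts n x L x m).
#' @export
admixed_dosages <- function(pop, n_anc = NULL) {
  L <- n_anc %||% max(pop$anc)
  n <- pop$n_ind; m <- ncol(pop$hap)
  i1 <- seq(1, 2 * n, 2); i2 <- seq(2, 2 * n, 2)
  dosage <- pop$hap[i1, , drop = FALSE] + pop$hap[i2, , drop = FALSE]
  part <- array(0L, dim = c(n, L, m))
  cnts <- array(0L, dim = c(n, L, m))
  for (l in seq_len(L)) {
    a1 <- pop$anc[i1, , drop = FALSE] == l
    a2 <- pop$anc[i2, , drop = FALSE] == l
    part[, l, ] <- a1 * pop$hap[i1, , drop = FALSE] +
                   a2 * pop$hap[i2, , drop = FALSE]
    cnts[, l, ] <- a1 + a2
  }
  list(dosage = dosage, partitioned = part, l_counts = cnts)
}

#' Pair panel haplotypes into a diploid single-continental cohort
#'
#' @param panel a `haplotype_panel`.
#' @return list(dosage n x m) with n = floor(haplotypes / 2).
#' @export
panel_dosages <- function(panel) {
  n <- nrow(panel$hap) %/% 2L
  i1 <- seq(1, 2 * n, 2); i2 <- seq(2, 2 * n, 2)
  list(dosage = panel$hap[i1, , drop = FALSE] + panel$hap[i2, , drop = FALSE])
}
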