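#' Local-ancestry-adjusted LD estimation
#'
#' For a locus pair (j, k) in an admixed cohort, the per-ancestry LD
#' coefficients are the coefficients of the ancestry-partitioned dosages in
#' the individual-level regression
#' C_j ~ M_k1 + M_k2 + L_k2 (+ intercept);
#' in a source panel the coefficient of M_k in C_j ~ M_k estimates
#' D / (g (1 - g)). Under the extended PSD model the two coincide; the
#' distance-binned concordance between them and the overlap with the local
#' ancestry segment-length distribution quantify where the model breaks.
#'
#' @name ldscan
NULL

#' Local-ancestry-adjusted LD coefficients at one pair
#'
#' @param c_j dosage at the target locus j (any variant; "causal" role).
#' @param m_part n x n_ancestries partitioned dosages at the marker k.
#' @param l_counts n x n_ancestries local ancestry counts at k.
#' @return list(coef, se): per-ancestry coefficient of M_kl and its OLS
#'   standard error; NA for an ancestry fixed at the locus.
#' @export
la_adjusted_ld <- function(c_j, m_part, l_counts) {
  m_part <- as.matrix(m_part); l_counts <- as.matrix(l_counts)
  L <- ncol(m_part)
  coefs <- ses <- rep(NA_real_, L)
  present <- apply(m_part, 2, function(v) stats::sd(v) > 0)
  if (!any(present)) return(list(coef = coefs, se = ses))
  use <- which(present)
  la_X <- l_counts[, -1, drop = FALSE]
  keep <- apply(la_X, 2, function(v) stats::sd(v) > 0)
  X <- cbind(1, m_part[, use, drop = FALSE], la_X[, keep, drop = FALSE])
  fit <- ols_fit(c_j, X)
  if (fit$degenerate) return(list(coef = coefs, se = ses))
  coefs[use] <- fit$coef[1 + seq_along(use)]
  ses[use] <- fit$se[1 + seq_along(use)]
  list(coef = coefs, se = ses)
}

#' Panel LD coefficient at one pair
#'
#' OLS slope (with intercept) of the target dosage on the marker dosage:
#' sample Cov(C, M) / Var(M), approximating D / (g (1-g)) under HWE.
#'
#' @param c_j,m_k diploid dosage vectors in the source cohort.
#' @return list(coef, se); NA when the marker is monomorphic.
#' @export
panel_ld <- function(c_j, m_k) {
  if (stats::sd(m_k) == 0) return(list(coef = NA_real_, se = NA_real_))
  fit <- ols_fit(c_j, cbind(1, m_k))
  if (fit$degenerate) return(list(coef = NA_real_, se = NA_real_))
  list(coef = unname(fit$coef[2]), se = unname(fit$se[2]))
}

#' Catalog locus pairs within a distance window
#'
#' All unordered pairs (j < k) with genetic distance below
#' `max_distance_cM`, uniformly subsampled to `max_pairs`; deterministic
#' given the seed.
#'
#' @param map a `genetic_map`.
#' @param max_distance_cM window in cM (> 0).
#' @param max_pairs cap on returned pairs (default: all).
#' @param seed subsampling seed (stage "pair_catalog").
#' @return data.frame(j, k, dist_bp, dist_cM).
#' @export
pair_catalog <- function(map, max_distance_cM, max_pairs = Inf, seed = NULL) {
  stopifnot(max_distance_cM > 0)
  cm <- map$morgans * 100
  m <- length(cm)
  hi <- findInterval(cm + max_distance_cM, cm)  # last k within window of j
  js <- rep.int(seq_len(m), pmax(hi - seq_len(m), 0L))
  ks <- unlist(lapply(seq_len(m), function(j) {
    if (hi[j] > j) seq.int(j + 1L, hi[j]) else integer(0)
  }), use.names = FALSE)
  pairs <- data.frame(j = js, k = ks,
                      dist_bp = map$bp[ks] - map$bp[js],
                      dist_cM = cm[ks] - cm[js])
  if (nrow(pairs) > max_pairs) {
    idx <- with_stage_seed(seed, "pair_catalog",
                           sort(sample.int(nrow(pairs), max_pairs)))
    pairs <- pairs[idx, , drop = FALSE]
  }
  pairs
}

#' Scan cataloged pairs in an admixed cohort and its source panels
#'
#' For every pair: the local-ancestry-adjusted coefficients in the admixed
#' cohort, the panel coefficients per ancestry, and the extended-PSD
#' predictions computed from the panel haplotype tallies.
#'
#' @param pairs a [pair_catalog()] data.frame.
#' @param dos [admixed_dosages()] of the admixed cohort.
#' @param panels list of `haplotype_panel`s (diploid views are built
#'   internally).
#' @return the pairs data.frame extended with adm_coef_l / adm_se_l /
#'   panel_coef_l / panel_se_l / pred_weight_l / pred_corr_l columns per
#'   ancestry l.
#' @export
ld_pair_scan <- function(pairs, dos, panels) {
  L <- length(panels)
  pd <- lapply(panels, panel_dosages)
  n_pair <- nrow(pairs)
  cols <- c("adm_coef", "adm_se", "panel_coef", "panel_se",
            "pred_weight", "pred_corr")
  vals <- array(NA_real_, dim = c(n_pair, length(cols), L))
  for (i in seq_len(n_pair)) {
    j <- pairs$j[i]; k <- pairs$k[i]
    adm <- la_adjusted_ld(dos$dosage[, j], dos$partitioned[, , k],
                          dos$l_counts[, , k])
    for (l in seq_len(L)) {
      pl <- panel_ld(pd[[l]]$dosage[, j], pd[[l]]$dosage[, k])
      hapl <- panels[[l]]$hap
      g <- mean(hapl[, k]); f <- mean(hapl[, j])
      D <- mean(hapl[, j] * hapl[, k]) - f * g
      pw <- if (g > 0 && g < 1) epsd_ld_weight(D, g) else NA_real_
      pc <- if (g > 0 && g < 1 && f > 0 && f < 1) {
        epsd_ld_corr(D, g, f)
      } else NA_real_
      vals[i, , l] <- c(adm$coef[l], adm$se[l], pl$coef, pl$se, pw, pc)
    }
  }
  out <- pairs
  for (l in seq_len(L)) {
    for (ci in seq_along(cols)) {
      out[[paste0(cols[ci], "_", l)]] <- vals[, ci, l]
    }
  }
  out
}

#' Distance-binned concordance of admixed and panel LD
#'
#' Per distance bin and ancestry, the Pearson correlation between the
#' local-ancestry-adjusted coefficients and the panel coefficients over the
#' pairs falling in the bin.
#'
#' @param pairs output of [ld_pair_scan()].
#' @param bin_edges_cM half-open bin edges, default
#'   c(0, 0.05, 0.1, 0.25, 0.5, 1, 2, 3).
#' @param min_pairs bins with fewer pairs are flagged.
#' @return data.frame(bin_lo, bin_hi, ancestry, r, n_pairs, flagged).
#' @export
concordance_by_distance <- function(pairs,
                                    bin_edges_cM = c(0, 0.05, 0.1, 0.25,
                                                     0.5, 1, 2, 3),
                                    min_pairs = 10) {
  L <- length(grep("^adm_coef_", names(pairs)))
  bins <- cut(pairs$dist_cM, bin_edges_cM, right = FALSE)
  res <- list()
  for (b in seq_len(length(bin_edges_cM) - 1)) {
    sel <- as.integer(bins) == b
    for (l in seq_len(L)) {
      x <- pairs[[paste0("adm_coef_", l)]][sel]
      y <- pairs[[paste0("panel_coef_", l)]][sel]
      ok <- is.finite(x) & is.finite(y)
      r <- if (sum(ok) >= 2 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        stats::cor(x[ok], y[ok])
      } else NA_real_
      res[[length(res) + 1]] <- data.frame(
        bin_lo = bin_edges_cM[b], bin_hi = bin_edges_cM[b + 1], ancestry = l,
        r = r, n_pairs = sum(ok), flagged = sum(ok) < min_pairs)
    }
  }
  do.call(rbind, res)
}

#' LD extent versus local-ancestry segment lengths
#'
#' Overlays the |LD correlation| vs distance point cloud on the
#' segment-length histogram (shared cM axis) and reports an overlap index:
#' the fraction of pairs with |r| above `r_threshold` at distances
#' exceeding the median interior segment length. A clear scale separation
#' (LD much shorter than segments) gives an index near 0.
#'
#' @param pairs output of [ld_pair_scan()].
#' @param seg [segment_lengths()] data.frame.
#' @param ancestry which ancestry's predicted correlation to use.
#' @param r_threshold correlation magnitude cutoff (default 0.1).
#' @param breaks histogram breaks in cM.
#' @return list(points, hist_counts, hist_breaks, median_segment_cM,
#'   overlap_index).
#' @export
ld_vs_segments <- function(pairs, seg, ancestry = 1, r_threshold = 0.1,
                           breaks = 30) {
  interior <- seg$length_cM[!seg$censored]
  med <- stats::median(interior)
  rr <- abs(pairs[[paste0("pred_corr_", ancestry)]])
  ok <- is.finite(rr)
  h <- graphics::hist(interior, breaks = breaks, plot = FALSE)
  far <- pairs$dist_cM[ok] > med
  idx <- if (any(far)) mean(rr[ok][far] > r_threshold) else 0
  list(points = data.frame(dist_cM = pairs$dist_cM[ok], abs_r = rr[ok]),
       hist_counts = h$counts, hist_breaks = h$breaks,
       median_segment_cM = med, overlap_index = idx)
}
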