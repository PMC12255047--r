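#' Genome scans: fit one model at every marker
#'
#' Thin loops over [fit_att()] / [fit_tractor()] returning tidy summary
#' tables that downstream experiments and the sumstats writer consume.
#'
#' @name scan
NULL

#' Standard-GWAS scan
#'
#' @param y trait vector.
#' @param dosage n x m total dosage matrix.
#' @param covariates optional covariate matrix.
#' @param markers marker indices to fit (default all).
#' @param excluded logical mask of markers to skip (near-monomorphic).
#' @return data.frame(marker, beta, se, chisq, p).
#' @export
att_scan <- function(y, dosage, covariates = NULL, markers = NULL,
                     excluded = NULL) {
  markers <- markers %||% seq_len(ncol(dosage))
  if (!is.null(excluded)) markers <- markers[!excluded[markers]]
  nm <- length(markers)
  beta <- se <- chisq <- p <- rep(NA_real_, nm)
  for (i in seq_len(nm)) {
    f <- fit_att(y, dosage[, markers[i]], covariates)
    beta[i] <- f$beta; se[i] <- f$se; chisq[i] <- f$chisq; p[i] <- f$p
  }
  data.frame(marker = markers, beta = beta, se = se, chisq = chisq, p = p)
}

#' Local-ancestry-aware scan with fixed-effects meta columns
#'
#' @param y trait vector.
#' @param partitioned n x n_ancestries x m partitioned dosage array.
#' @param l_counts n x n_ancestries x m local ancestry count array.
#' @param covariates optional covariate matrix.
#' @param markers,excluded as in [att_scan()].
#' @return data.frame with per-ancestry beta_l / se_l / chisq_l, the
#'   combined Wald chisq/df/p, and FE meta-analysis beta/chisq/p/Q.
#' @export
tractor_scan <- function(y, partitioned, l_counts, covariates = NULL,
                         markers = NULL, excluded = NULL) {
  L <- dim(partitioned)[2]
  markers <- markers %||% seq_len(dim(partitioned)[3])
  if (!is.null(excluded)) markers <- markers[!excluded[markers]]
  nm <- length(markers)
  comb <- matrix(NA_real_, nm, 3,
                 dimnames = list(NULL, c("chisq_combined", "df",
                                         "p_combined")))
  per_l <- array(NA_real_, dim = c(nm, 3, L))
  fe <- matrix(NA_real_, nm, 5,
               dimnames = list(NULL, c("beta_fe", "se_fe", "chisq_fe",
                                       "p_fe", "Q")))
  for (i in seq_len(nm)) {
    k <- markers[i]
    f <- suppressMessages(
      fit_tractor(y, partitioned[, , k], l_counts[, , k], covariates))
    if (f$degenerate) next
    comb[i, ] <- c(f$chisq_combined, f$df, f$p_combined)
    for (l in seq_len(L)) per_l[i, , l] <- c(f$beta[l], f$se[l], f$chisq[l])
    if (sum(!is.na(f$beta)) >= 1) {
      m <- suppressMessages(fe_combine(f$beta, f$se))
      fe[i, ] <- c(m$beta_fe, m$se_fe, m$chisq_fe, m$p_fe, m$Q)
    }
  }
  out <- data.frame(marker = markers, comb)
  for (l in seq_len(L)) {
    out[[paste0("beta_", l)]] <- per_l[, 1, l]
    out[[paste0("se_", l)]] <- per_l[, 2, l]
    out[[paste0("chisq_", l)]] <- per_l[, 3, l]
  }
  cbind(out, fe)
}
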