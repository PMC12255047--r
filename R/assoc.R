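#' Association models for admixed cohorts
#'
#' Two ordinary-least-squares models are fit per marker. The standard GWAS
#' regression (Armitage trend test, ATT) regresses the trait on the total
#' allele dosage plus covariates. The local-ancestry-aware (Tractor-style)
#' regression splits the dosage by local ancestry, adding n_L - 1 local
#' ancestry covariate columns (one is dropped because the diploid counts sum
#' to 2). Standard errors are the classical homoskedastic OLS ones, which
#' are what the closed-form theory predicts.
#'
#' @name assoc
NULL

#' Ancestry covariate columns for regression
#'
#' Global-ancestry proportions with the first (reference) column dropped for
#' identifiability against the intercept; constant columns are removed.
#'
#' @param P global-ancestry matrix, or NULL.
#' @return a numeric matrix with 0 or more columns.
#' @export
ancestry_covariates <- function(P) {
  if (is.null(P)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  P <- as.matrix(P)
  X <- P[, -1, drop = FALSE]
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X[, keep, drop = FALSE]
}

#' Fit the standard GWAS (ATT) regression at one marker
#'
#' @param y trait vector.
#' @param m total allele dosage at the marker (0/1/2).
#' @param covariates optional covariate matrix (ancestry proportions etc.;
#'   an intercept is always added).
#' @return an `att_result`: list(beta, se, chisq, p, n, degenerate).
#' @export
fit_att <- function(y, m, covariates = NULL) {
  X <- cbind(intercept = 1, marker = m)
  if (!is.null(covariates) && length(covariates)) X <- cbind(X, covariates)
  fit <- ols_fit(y, X)
  if (fit$degenerate) {
    return(structure(list(beta = NA_real_, se = NA_real_, chisq = NA_real_,
                          p = NA_real_, n = length(y), degenerate = TRUE),
                     class = "att_result"))
  }
  b <- fit$coef[2]; s <- fit$se[2]
  if (!is.na(fit$sigma2) && fit$sigma2 <= 1e-20 * max(1, mean(y^2))) {
    # numerically exact fit: the statistic is 0/0 noise unless b is real
    b <- if (abs(b) < 1e-10) 0 else b
    s <- 0
  }
  chisq <- wald_1df(b, s)
  structure(list(beta = unname(b), se = unname(s), chisq = chisq,
                 p = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 n = fit$n, sigma2 = fit$sigma2, degenerate = FALSE),
            class = "att_result")
}

#' Fit the local-ancestry-aware (Tractor) regression at one marker
#'
#' Joint OLS of the trait on the ancestry-partitioned dosages M_ikl (one
#' column per ancestry present in the cohort at this locus), the local
#' ancestry counts L_ikl for all but the reference ancestry, an intercept
#' and covariates. An ancestry with no chromosome copies at the locus is
#' flagged NA and the combined Wald test falls back to the present
#' ancestries with reduced degrees of freedom.
#'
#' @param y trait vector.
#' @param m_part n x n_ancestries matrix of ancestry-partitioned dosages.
#' @param l_counts n x n_ancestries matrix of diploid local ancestry counts.
#' @param covariates optional covariate matrix.
#' @return a `tractor_result`: per-ancestry beta/se/chisq/p, gamma and
#'   gamma_se for non-reference local-ancestry columns, the estimated
#'   covariance block `vcov_beta`, combined chisq/df/p, n, degenerate flag.
#' @export
fit_tractor <- function(y, m_part, l_counts, covariates = NULL) {
  m_part <- as.matrix(m_part); l_counts <- as.matrix(l_counts)
  L <- ncol(m_part)
  present <- colSums(l_counts) > 0
  if (!any(present)) stop("no ancestry present at this locus")
  if (sum(present) < L) {
    message("ancestry absent at this locus: ",
            paste(which(!present), collapse = ","), "; reduced-df fallback")
  }
  use <- which(present)
  # reference = first present ancestry; LA columns for the others, dropping
  # any constant column (e.g. a locus where everyone carries 2 copies)
  la_cols <- use[-1]
  la_X <- l_counts[, la_cols, drop = FALSE]
  keep_la <- apply(la_X, 2, function(v) stats::sd(v) > 0)
  la_X <- la_X[, keep_la, drop = FALSE]
  X <- cbind(1, m_part[, use, drop = FALSE], la_X)
  n_m <- length(use)
  if (!is.null(covariates) && length(covariates)) X <- cbind(X, covariates)
  fit <- ols_fit(y, X)
  beta <- se <- rep(NA_real_, L)
  if (fit$degenerate) {
    return(structure(list(beta = beta, se = se, chisq = rep(NA_real_, L),
                          p = rep(NA_real_, L), gamma = NULL,
                          gamma_se = NULL, vcov_beta = NULL,
                          chisq_combined = NA_real_, df = NA_integer_,
                          p_combined = NA_real_, n = length(y),
                          degenerate = TRUE),
                     class = "tractor_result"))
  }
  idx_m <- 1 + seq_len(n_m)
  beta[use] <- fit$coef[idx_m]
  se[use] <- fit$se[idx_m]
  Vb <- fit$vcov[idx_m, idx_m, drop = FALSE]
  gamma_idx <- if (ncol(la_X)) 1 + n_m + seq_len(ncol(la_X)) else integer(0)
  chisq <- vapply(seq_len(L), function(l) wald_1df(beta[l], se[l]), 0)
  comb <- wald_quadform(beta[use], Vb)
  structure(list(beta = beta, se = se, chisq = chisq,
                 p = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 gamma = fit$coef[gamma_idx], gamma_se = fit$se[gamma_idx],
                 vcov_beta = Vb, chisq_combined = comb$stat, df = comb$df,
                 p_combined = comb$p, n = fit$n, sigma2 = fit$sigma2,
                 ancestries = use, degenerate = FALSE),
            class = "tractor_result")
}

#' @keywords internal
wald_quadform <- function(beta, V) {
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e) NULL)
  if (is.null(Vi)) return(list(stat = NA_real_, df = NA_integer_, p = NA_real_))
  stat <- drop(t(beta) %*% Vi %*% beta)
  df <- length(beta)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Combined Wald test of all ancestry-specific effects
#'
#' beta' V^-1 beta over the non-NA ancestries of a Tractor fit, with degrees
#' of freedom equal to their number. The statistic is invariant under
#' reordering ancestries, and for a diagonal covariance it equals
#' sum((beta_l / se_l)^2).
#'
#' @param result a `tractor_result`.
#' @return list(stat, df, p).
#' @export
wald_combined <- function(result) {
  ok <- !is.na(result$beta)
  if (!any(ok)) return(list(stat = NA_real_, df = NA_integer_, p = NA_real_))
  wald_quadform(result$beta[ok], result$vcov_beta)
}
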