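#' Fixed-effects meta-analysis of ancestry-specific estimates
#'
#' Because the ancestry-specific estimates from one local-ancestry-aware
#' regression are independent, they can be pooled exactly like independent
#' study estimates: inverse-variance weights w_l = 1/se_l^2, pooled
#' beta_FE = sum(w b) / sum(w), 1-df chi-square T_FE = beta_FE^2 sum(w),
#' and Cochran heterogeneity Q = sum(w (b_l - beta_FE)^2) on n_L - 1 df.
#' The exact identity T_FE + Q = sum((b_l/se_l)^2) ties FE to the combined
#' multi-df Wald statistic: under equal true effects FE recovers the same
#' statistic while spending only one degree of freedom.
#'
#' NA estimates are dropped, never imputed; a single remaining estimate is
#' passed through with Q = 0.
#'
#' @param betas per-ancestry estimates.
#' @param ses their standard errors (positive).
#' @return a `meta_result`: list(beta_fe, se_fe, chisq_fe, p_fe, Q, df_Q,
#'   p_Q, n_used).
#' @export
fe_combine <- function(betas, ses) {
  ok <- !is.na(betas) & !is.na(ses)
  if (!any(ok)) stop("no usable estimates")
  b <- betas[ok]; s <- ses[ok]
  if (any(s <= 0)) stop("standard errors must be positive")
  if (length(b) == 1) {
    message("single estimate: passthrough with Q = 0")
    return(structure(list(beta_fe = b, se_fe = s, chisq_fe = (b / s)^2,
                          p_fe = stats::pchisq((b / s)^2, 1, lower.tail = FALSE),
                          Q = 0, df_Q = 0L, p_Q = NA_real_, n_used = 1L),
                     class = "meta_result"))
  }
  w <- 1 / s^2
  bfe <- sum(w * b) / sum(w)
  chisq <- bfe^2 * sum(w)
  Q <- sum(w * (b - bfe)^2)
  structure(list(beta_fe = bfe, se_fe = 1 / sqrt(sum(w)), chisq_fe = chisq,
                 p_fe = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 Q = Q, df_Q = length(b) - 1L,
                 p_Q = stats::pchisq(Q, length(b) - 1L, lower.tail = FALSE),
                 n_used = length(b)),
            class = "meta_result")
}

#' Cross-ancestry independence diagnostic
#'
#' Pearson correlation between replicated per-ancestry estimates with a
#' Fisher-z normal-approximation confidence interval; independence is
#' supported when the interval covers 0.
#'
#' @param b1,b2 estimate vectors over replicates (>= 100).
#' @param level confidence level.
#' @return list(r, ci, n, independent).
#' @export
independence_diagnostic <- function(b1, b2, level = 0.99) {
  stopifnot(length(b1) == length(b2))
  n <- length(b1)
  if (n < 100) stop("need at least 100 replicates")
  if (stats::sd(b1) == 0 || stats::sd(b2) == 0) {
    return(list(r = NA_real_, ci = c(NA_real_, NA_real_), n = n,
                independent = NA))
  }
  r <- stats::cor(b1, b2)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  ci <- tanh(c(z - hw, z + hw))
  list(r = r, ci = ci, n = n, independent = ci[1] <= 0 && ci[2] >= 0)
}
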