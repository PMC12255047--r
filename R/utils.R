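`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a run seed
#'
#' Each simulation stage (global ancestry, local ancestry, alleles, traits,
#' mating, ...) draws from its own substream so that stages can be
#' regenerated independently. The mapping is deterministic in (seed, stage)
#' and always lies in [1, 2^31 - 2].
#'
#' @param seed integer run seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 32749
  as.integer((((abs(seed) %% 32749) * 65521 + h * 2654435 + 1)) %% 2147483647)
}

#' @rdname stage_seed
#' @param expr expression evaluated after seeding the stage substream
#'   (a NULL seed leaves the generator untouched).
#' @export
with_stage_seed <- function(seed, stage, expr) {
  if (!is.null(seed)) set.seed(stage_seed(seed, stage))
  expr
}

#' @keywords internal
#' OLS by normal equations; designs here are tiny (p <= ~8) so the Cholesky
#' of X'X is both the fastest and the numerically adequate route.
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) || any(!is.finite(R))) {
    return(list(degenerate = TRUE, n = nrow(X)))
  }
  XtXinv <- chol2inv(R)
  coef <- drop(XtXinv %*% crossprod(X, y))
  rss <- sum((y - drop(X %*% coef))^2)
  df <- nrow(X) - ncol(X)
  sigma2 <- if (df > 0) rss / df else NA_real_
  vcov <- sigma2 * XtXinv
  list(degenerate = FALSE, coef = coef, se = sqrt(pmax(diag(vcov), 0)),
       vcov = vcov, sigma2 = sigma2, df = df, n = nrow(X))
}

#' @keywords internal
wald_1df <- function(beta, se) {
  if (!is.finite(beta) || !is.finite(se)) return(NA_real_)
  if (se == 0) return(if (beta == 0) 0 else Inf)
  (beta / se)^2
}
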