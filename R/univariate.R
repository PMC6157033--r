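#' Per-CpG linear-model association test
#'
#' Regresses the trait on the confounders plus a single CpG and reports the
#' two-sided t-test on the CpG coefficient — the classic univariate EWAS
#' test for unrelated samples.
#'
#' @param x Trait vector.
#' @param C Optional confounder matrix (intercept added).
#' @param y_cpg Methylation vector for one CpG.
#' @param cpg_id Identifier carried into the result row.
#' @return One-row association-result data frame (`method =
#'   "univariate_lm"`, `statistic` = t, `df_or_neigs` = residual df).
#' @export
cpg_lm_test <- function(x, C = NULL, y_cpg, cpg_id = "cpg") {
  n <- length(x)
  C <- prep_confounders(C, n)
  if (stats::sd(y_cpg) < 1e-12) {
    warning("constant CpG; p-value set to 1")
    return(association_result(cpg_id, "univariate_lm", 0,
                              n - ncol(C) - 1L, 1))
  }
  X <- cbind(C, y_cpg)
  qX <- qr(X)
  if (qX$rank < ncol(X)) stop("design matrix [C, y_cpg] is rank deficient")
  coefs <- qr.coef(qX, x)
  res <- qr.resid(qX, x)
  df <- n - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv_last <- solve(crossprod(X))[ncol(X), ncol(X)]
  tval <- coefs[ncol(X)] / sqrt(s2 * XtXinv_last)
  pv <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  association_result(cpg_id, "univariate_lm", tval, df, pv)
}

#' Vectorized per-CpG linear-model tests
#'
#' Same test as [cpg_lm_test()] applied to every column of a methylation
#' matrix at once, via partial correlations of confounder residuals:
#' `t_j = r_j sqrt(df / (1 - r_j^2))` with `df = n - r - 1`.
#'
#' @inheritParams cpg_lm_test
#' @param Y Methylation matrix (samples x CpGs).
#' @return Association-result data frame, one row per CpG.
#' @export
cpg_lm_test_many <- function(x, C = NULL, Y) {
  n <- length(x)
  C <- prep_confounders(C, n)
  qC <- qr(C)
  xt <- qr.resid(qC, x)
  Yt <- qr.resid(qC, as.matrix(Y))
  df <- n - ncol(C) - 1L
  ssy <- colSums(Yt^2)
  ok <- ssy > 1e-12
  r <- rep(0, ncol(Yt))
  r[ok] <- as.numeric(crossprod(xt, Yt[, ok, drop = FALSE])) /
    sqrt(sum(xt^2) * ssy[ok])
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r * sqrt(df / (1 - r^2))
  pv <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  pv[!ok] <- 1
  tval[!ok] <- 0
  ids <- colnames(Y)
  if (is.null(ids)) ids <- paste0("cpg", seq_len(ncol(Y)))
  association_result(ids, "univariate_lm", tval, df, pv)
}

#' Per-CpG kinship linear mixed-model test
#'
#' Fits `x = [C, y_cpg] beta + g + e` with `g ~ N(0, sigma_g2 * 2 Phi)` and
#' reports the Wald test on the CpG coefficient, referred to a
#' t distribution with `n - p` degrees of freedom (`p` = fixed-effect
#' columns) so that the test reduces exactly to the ordinary linear model
#' when the kinship matrix carries no structure.  By default the variance
#' components are re-estimated (REML) under the alternative for every CpG;
#' with `fast = TRUE` the components of a covariate-only null model are
#' reused and only the generalized-least-squares fixed effects are refitted.
#'
#' @inheritParams cpg_lm_test
#' @param kin Kinship matrix aligned with `x`.
#' @param fast Reuse null-model variance components (default `FALSE`).
#' @param null Optional `"vc_null"` from [fit_null_lmm()], required (and
#'   only used) when `fast = TRUE`.
#' @param kin_eigen Optional precomputed `eigen(2 * kin)`, reused across
#'   CpGs when scanning a whole array.
#' @return One-row association-result data frame (`method =
#'   "univariate_lmm"`, `statistic` = Wald z).
#' @export
cpg_lmm_test <- function(x, C = NULL, y_cpg, kin, cpg_id = "cpg",
                         fast = FALSE, null = NULL, kin_eigen = NULL) {
  n <- length(x)
  C <- prep_confounders(C, n)
  if (stats::sd(y_cpg) < 1e-12) {
    warning("constant CpG; p-value set to 1")
    return(association_result(cpg_id, "univariate_lmm", 0, 1L, 1))
  }
  X <- cbind(C, y_cpg)
  if (qr(X)$rank < ncol(X)) stop("design matrix [C, y_cpg] is rank deficient")
  if (fast) {
    if (is.null(null) || is.null(null$kin_eigen))
      stop("fast = TRUE requires a kinship null model")
    d <- null$kin_eigen$values
    U <- null$kin_eigen$vectors
    w <- 1 / (null$sigma_g2 * d + null$sigma_e2)
    Xt <- crossprod(U, X)
    xt <- as.numeric(crossprod(U, x))
  } else {
    alt <- fit_null_lmm(x, C = X[, -1, drop = FALSE], kin = kin,
                        kin_eigen = kin_eigen, compute_P0 = FALSE)
    d <- alt$kin_eigen$values
    U <- alt$kin_eigen$vectors
    w <- 1 / (alt$sigma_g2 * d + alt$sigma_e2)
    Xt <- crossprod(U, X)
    xt <- as.numeric(crossprod(U, x))
  }
  XtW <- Xt * w
  A <- crossprod(Xt, XtW)
  Ainv <- solve(A)
  bhat <- Ainv %*% crossprod(XtW, xt)
  j <- ncol(X)
  z <- bhat[j] / sqrt(Ainv[j, j])
  df <- n - ncol(X)
  pv <- 2 * stats::pt(abs(z), df, lower.tail = FALSE)
  association_result(cpg_id, "univariate_lmm", z, df, pv)
}
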