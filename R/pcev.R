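## internal: append an intercept and check rank of the confounder design
prep_confounders <- function(C, n) {
  if (is.null(C)) C <- matrix(numeric(0), n, 0)
  C <- as.matrix(C)
  if (nrow(C) != n) stop("confounder rows do not match sample count")
  C <- cbind(`(Intercept)` = 1, C)
  if (qr(C)$rank < ncol(C)) stop("confounder matrix is rank deficient")
  C
}

#' Fit the principal component of explained variation (PCEV) for a block
#'
#' Finds the loading vector `w` maximizing \eqn{h^2(w)}, the proportion of
#' variance of the methylation block `Y w` that is explained by the trait
#' `x` after adjusting for confounders `C`.  Columns of `Y` and `x` are
#' first residualized on `C` (ordinary least squares with an intercept
#' always included); `V_G` is the cross-product of fitted values from the
#' regression of residual `Y` on residual `x`, `V_R` the cross-product of
#' the remaining residuals; `w` is the leading eigenvector of
#' \eqn{V_R^{-1} V_G}, solved through the Cholesky factor of `V_R` (with a
#' small diagonal jitter retried on failure) so that the eigenproblem is
#' symmetric.  With leading eigenvalue `d`, \eqn{h^2 = d / (1 + d)}.
#'
#' @param Y Numeric matrix `n x p` of block methylation values.
#' @param x Numeric trait vector of length `n`.
#' @param C Optional `n x r0` confounder matrix (an intercept is added).
#' @return List of class `"pcev_fit"`: loadings `w`, `h2`, the score vector
#'   `component` (`= Y_residualized %*% w`), `V_G`, `V_R`, and the counts
#'   `n`, `p`, `r` (confounder columns including the intercept).
#' @export
fit_pcev <- function(Y, x, C = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  if (length(x) != n) stop("trait length does not match Y")
  C <- prep_confounders(C, n)
  r <- ncol(C)
  if (p > n - r - 2)
    stop("block too large for PCEV (p > n - r - 2); split the block first")
  qC <- qr(C)
  Yt <- qr.resid(qC, Y)
  xt <- qr.resid(qC, x)
  if (sum(xt^2) < 1e-12) stop("trait is collinear with the confounders")
  bhat <- crossprod(xt, Yt) / sum(xt^2)        # 1 x p slopes
  fit <- xt %*% bhat
  res <- Yt - fit
  Vg <- crossprod(fit)
  Vr <- crossprod(res)
  R <- tryCatch(chol(Vr), error = function(e) {
    chol(Vr + diag(1e-10 * mean(diag(Vr)), p))
  })
  ## eigen of Vr^{-1} Vg via the congruent symmetric matrix R^{-T} Vg R^{-1}
  B <- forwardsolve(t(R), Vg)
  S <- t(forwardsolve(t(R), t(B)))
  eS <- eigen((S + t(S)) / 2, symmetric = TRUE)
  d <- max(eS$values[1], 0)
  w <- backsolve(R, eS$vectors[, 1])
  structure(list(w = as.numeric(w), h2 = d / (1 + d), d = d,
                 component = as.numeric(Yt %*% w),
                 V_G = Vg, V_R = Vr, n = n, p = p, r = r),
            class = "pcev_fit")
}

#' Analytic PCEV p-value
#'
#' Tests the null that the block explains none of its variance through the
#' trait (\eqn{h^2(w) = 0}).  Because the hypothesis is rank one (a single
#' trait), the largest root `d` of \eqn{V_R^{-1} V_G} has an exact
#' F transformation under Gaussian residuals:
#' \deqn{F = d (n - r - p) / p \sim F(p,\; n - r - p),}
#' the multivariate analogue of Hotelling's T-squared for one predictor.
#'
#' @param fit A `"pcev_fit"` object from [fit_pcev()].
#' @return Upper-tail p-value.
#' @export
pcev_test_analytic <- function(fit) {
  df2 <- fit$n - fit$r - fit$p
  if (df2 <= 0) stop("nonpositive denominator degrees of freedom")
  Fstat <- fit$d * df2 / fit$p
  stats::pf(Fstat, fit$p, df2, lower.tail = FALSE)
}

#' Permutation PCEV p-value
#'
#' Permutes the confounder-residualized trait and recomputes \eqn{h^2} for
#' each permutation; the p-value is `(1 + #{h2_perm >= h2_obs}) /
#' (n_perm + 1)`, so the smallest attainable value is `1 / (n_perm + 1)`.
#'
#' @inheritParams fit_pcev
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return Permutation p-value.
#' @export
pcev_test_permutation <- function(Y, x, C = NULL, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  C <- prep_confounders(C, n)
  qC <- qr(C)
  Yt <- qr.resid(qC, Y)
  xt <- qr.resid(qC, x)
  h2_of <- function(xv) {
    b <- crossprod(xv, Yt) / sum(xv^2)
    fit <- xv %*% b
    res <- Yt - fit
    Vr <- crossprod(res)
    R <- tryCatch(chol(Vr), error = function(e) {
      chol(Vr + diag(1e-10 * mean(diag(Vr)), ncol(Yt)))
    })
    B <- forwardsolve(t(R), crossprod(fit))
    S <- t(forwardsolve(t(R), t(B)))
    d <- max(eigen((S + t(S)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values[1], 0)
    d / (1 + d)
  }
  h2_obs <- h2_of(xt)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (h2_of(sample(xt)) >= h2_obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_perm + 1)
}
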