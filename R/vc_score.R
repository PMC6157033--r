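#' Covariate-only null model for unrelated samples
#'
#' Ordinary least squares of the trait on the confounders (intercept always
#' included).  The residual variance uses the REML-type denominator
#' `n - r`, and the score-projection matrix is
#' \eqn{P_0 = (I - H) / \hat\sigma_e^2} with `H` the hat matrix of `C`, so
#' that \eqn{P_0 C = 0} and \eqn{P_0 V P_0 = P_0}.
#'
#' @param x Numeric trait vector.
#' @param C Optional confounder matrix (intercept added automatically).
#' @return List of class `"vc_null"` with elements `beta`, `sigma_g2` (0),
#'   `sigma_e2`, `P0`, `loglik` (REML), `C`, `n`, `r`.
#' @export
fit_null_lm <- function(x, C = NULL) {
  n <- length(x)
  C <- prep_confounders(C, n)
  r <- ncol(C)
  qC <- qr(C)
  beta <- qr.coef(qC, x)
  res <- qr.resid(qC, x)
  rss <- sum(res^2)
  if (rss < 1e-12 * max(sum(x^2), 1))
    stop("trait is (numerically) an exact linear function of the confounders")
  sigma_e2 <- rss / (n - r)
  H <- tcrossprod(qr.Q(qC)[, seq_len(r), drop = FALSE])
  P0 <- (diag(n) - H) / sigma_e2
  loglik <- -0.5 * ((n - r) * log(sigma_e2) + (n - r))
  structure(list(beta = beta, sigma_g2 = 0, sigma_e2 = sigma_e2,
                 P0 = P0, loglik = loglik, C = C, n = n, r = r,
                 boundary = FALSE),
            class = "vc_null")
}

## REML profile criterion for the variance ratio delta = sigma_g2 / sigma_e2,
## in the eigenbasis of 2*Phi (d = eigenvalues, xt/Ct rotated data).
reml_profile <- function(log_delta, d, xt, Ct) {
  delta <- exp(log_delta)
  n <- length(xt); r <- ncol(Ct)
  w <- 1 / (1 + delta * d)
  CtW <- Ct * w
  A <- crossprod(Ct, CtW)
  b <- solve(A, crossprod(CtW, xt))
  res <- xt - Ct %*% b
  rss <- sum(w * res^2)
  sigma_e2 <- rss / (n - r)
  ll <- -0.5 * ((n - r) * log(sigma_e2) - sum(log(w)) +
                  determinant(A, logarithm = TRUE)$modulus + (n - r))
  list(loglik = as.numeric(ll), sigma_e2 = sigma_e2, beta = b, w = w)
}

#' Kinship linear mixed-effects null model
#'
#' Fits `x = C beta + g + e` with `g ~ N(0, sigma_g2 * 2 Phi)` and
#' `e ~ N(0, sigma_e2 I)` by restricted maximum likelihood.  The variance
#' ratio `delta = sigma_g2 / sigma_e2` is profiled on a log-spaced grid over
#' `[1e-5, 1e5]` and refined by golden-section search, using the spectral
#' decomposition of `2 Phi` computed once.  The projection
#' \eqn{P_0 = V^{-1} - V^{-1} C (C' V^{-1} C)^{-1} C' V^{-1}} is assembled
#' from the fitted `V`.  A `boundary` flag is set when the optimum sits at
#' the edge of the search interval (e.g. a zero familial component).
#'
#' @inheritParams fit_null_lm
#' @param kin Kinship matrix aligned with `x` (pairwise coefficients
#'   \eqn{\phi}); `2 * kin` must be positive semi-definite.
#' @param kin_eigen Optional precomputed `eigen(2 * kin)` (list with
#'   `values`, `vectors`), reused across many fits on the same cohort.
#' @param compute_P0 Set `FALSE` to skip assembling the `n x n` projection
#'   when only variance components and fixed effects are needed.
#' @return List of class `"vc_null"`; `sigma_g2 > 0` marks the family model.
#' @export
fit_null_lmm <- function(x, C = NULL, kin, kin_eigen = NULL,
                         compute_P0 = TRUE) {
  n <- length(x)
  C <- prep_confounders(C, n)
  r <- ncol(C)
  if (is.null(kin_eigen)) {
    if (nrow(kin) != n) stop("kinship dimension does not match trait length")
    A2 <- 2 * kin
    eg <- eigen((A2 + t(A2)) / 2, symmetric = TRUE)
    if (min(eg$values) < -1e-6 * max(eg$values))
      stop("2*kinship matrix is not positive semi-definite")
  } else {
    eg <- kin_eigen
    if (length(eg$values) != n) stop("kin_eigen dimension mismatch")
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  xt <- as.numeric(crossprod(U, x))
  Ct <- crossprod(U, C)
  grid <- seq(log(1e-5), log(1e5), length.out = 41)
  ll <- vapply(grid, function(g) reml_profile(g, d, xt, Ct)$loglik, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(g) reml_profile(g, d, xt, Ct)$loglik,
                         c(lo, hi), maximum = TRUE, tol = 1e-8)
  log_delta <- opt$maximum
  boundary <- i == 1 || i == length(grid)
  if (boundary && i == 1 && ll[1] >= opt$objective) log_delta <- grid[1]
  if (boundary && i == length(grid) && ll[i] >= opt$objective)
    log_delta <- grid[i]
  prof <- reml_profile(log_delta, d, xt, Ct)
  delta <- exp(log_delta)
  sigma_e2 <- prof$sigma_e2
  sigma_g2 <- delta * sigma_e2
  if (boundary && i == 1) sigma_g2 <- max(sigma_g2, 0)
  ## P0 in the eigenbasis: (W - W Ct (Ct' W Ct)^{-1} Ct' W) / sigma_e2
  P0 <- NULL
  w <- prof$w
  if (compute_P0) {
    CtW <- Ct * w
    Ainv <- solve(crossprod(Ct, CtW))
    M <- diag(w) - CtW %*% Ainv %*% t(CtW)
    P0 <- U %*% (M / sigma_e2) %*% t(U)
  }
  beta <- as.numeric(prof$beta)
  names(beta) <- colnames(C)
  structure(list(beta = beta, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 P0 = P0, loglik = prof$loglik, C = C, n = n, r = r,
                 delta = delta, boundary = boundary,
                 kin_eigen = list(values = d, vectors = U)),
            class = "vc_null")
}

#' Variance-component (SKAT-type) score test for a CpG block
#'
#' Treats the block as a random effect acting on the variance of the trait:
#' with `Z` the column-centered (optionally unit-variance scaled and
#' weighted) block matrix and kernel `K = Z Z'`, the score statistic is
#' \deqn{Q = x' P_0 K P_0 x,}
#' whose null distribution is the mixture \eqn{\sum_j \lambda_j \chi^2_1}
#' with \eqn{\lambda_j} the nonzero eigenvalues of
#' \eqn{P_0^{1/2} K P_0^{1/2}} (computed as the eigenvalues of
#' `Z' P0 Z`).  The tail probability uses [davies_pvalue()] with its Liu
#' moment-matching fallback.
#'
#' @param null A `"vc_null"` model from [fit_null_lm()] or [fit_null_lmm()];
#'   the same `x` used to fit it must be supplied.
#' @param x Trait vector the null model was fitted to.
#' @param Y_block `n x p` methylation block aligned with `x`.
#' @param weights Optional nonnegative per-CpG weights (default all 1).
#' @param scale_option `"center"` (default) or `"standardize"` for the block
#'   columns.
#' @return List of class `"vc_quadform"`: `Q`, `eigenvalues`, `pvalue`,
#'   `method_used` (`"davies"` or `"liu"`), `n_eigs`.
#' @export
vc_score_test <- function(null, x, Y_block, weights = NULL,
                          scale_option = c("center", "standardize")) {
  scale_option <- match.arg(scale_option)
  Y_block <- as.matrix(Y_block)
  p <- ncol(Y_block)
  if (p == 0) stop("empty CpG block")
  if (nrow(Y_block) != null$n) stop("block rows do not match the null model")
  if (is.null(weights)) weights <- rep(1, p)
  if (length(weights) != p || any(weights < 0))
    stop("weights must be nonnegative, one per CpG")
  sds <- apply(Y_block, 2, stats::sd)
  if (all(sds < 1e-12)) {
    warning("all CpGs in block are constant; p-value set to 1")
    return(structure(list(Q = 0, eigenvalues = numeric(0), pvalue = 1,
                          method_used = "degenerate", n_eigs = 0L),
                     class = "vc_quadform"))
  }
  Z <- scale(Y_block, center = TRUE,
             scale = if (scale_option == "standardize") sds else FALSE)
  Z[, sds < 1e-12] <- 0
  Z <- sweep(Z, 2, sqrt(weights), `*`)
  P0x <- null$P0 %*% x
  s <- crossprod(Z, P0x)
  Q <- sum(s^2)
  B <- crossprod(Z, null$P0 %*% Z)
  lam <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam, 0)]
  if (!length(lam)) {
    warning("kernel has no positive eigenvalues; p-value set to 1")
    return(structure(list(Q = Q, eigenvalues = numeric(0), pvalue = 1,
                          method_used = "degenerate", n_eigs = 0L),
                     class = "vc_quadform"))
  }
  pv <- davies_pvalue(Q, lam)
  structure(list(Q = Q, eigenvalues = lam, pvalue = pv$pvalue,
                 method_used = pv$method_used, n_eigs = length(lam)),
            class = "vc_quadform")
}

#' Tail probability of a positive mixture of 1-df chi-squares
#'
#' Computes \eqn{P(\sum_j \lambda_j \chi^2_1 > q)} by numerical inversion of
#' the characteristic function (Imhof's integral),
#' \deqn{P = 1/2 + \pi^{-1} \int_0^\infty \sin\theta(u) / (u\,\rho(u))\, du,}
#' with \eqn{\theta(u) = \frac12\sum_j \arctan(\lambda_j u) - qu/2} and
#' \eqn{\rho(u) = \prod_j (1 + \lambda_j^2 u^2)^{1/4}}, integrated to
#' absolute accuracy `1e-9`.  If the integrator fails or returns a value
#' outside `(0, 1]`, the Liu moment-matching approximation (first three
#' cumulants matched to a scaled noncentral chi-square) is used instead and
#' reported in `method_used`.
#'
#' @param q Observed statistic.
#' @param lambdas Mixture weights; nonpositive values (numerical noise) are
#'   dropped, and at least one must be positive.
#' @return List with `pvalue` and `method_used` (`"davies"` or `"liu"`).
#' @export
davies_pvalue <- function(q, lambdas) {
  lam <- lambdas[lambdas > 0]
  if (!length(lam)) stop("all mixture weights are nonpositive")
  p <- tryCatch(imhof_prob(q, lam), error = function(e) NA_real_)
  if (is.na(p) || p <= 0 || p > 1)
    return(list(pvalue = liu_pvalue(q, lam), method_used = "liu"))
  list(pvalue = p, method_used = "davies")
}

## Imhof's inversion integral evaluated piecewise between the zeros of the
## oscillating factor sin(theta(u)); theta is unimodal (its derivative is
## strictly decreasing), so past the final positive crossing the chunk
## integrals form a strictly alternating series whose tail is summed by
## Euler transformation (repeated averaging of partial sums).  Absolute
## accuracy ~1e-10 on moderate tail probabilities.
imhof_prob <- function(q, lam, n_alt = 80L) {
  theta1 <- function(u) 0.5 * sum(atan(lam * u)) - 0.5 * q * u
  dtheta1 <- function(u) 0.5 * sum(lam / (1 + (lam * u)^2)) - 0.5 * q
  f <- function(u) {
    out <- numeric(length(u))
    nz <- u > 0
    uu <- u[nz]
    th <- 0.5 * colSums(atan(outer(lam, uu))) - 0.5 * q * uu
    lr <- 0.25 * colSums(log1p(outer(lam^2, uu^2)))
    out[nz] <- sin(th) / (uu * exp(lr))
    out[!nz] <- 0.5 * (sum(lam) - q)
    out
  }
  chunk <- function(a, b)
    stats::integrate(f, a, b, rel.tol = 1e-11, abs.tol = 1e-13,
                     subdivisions = 200L, stop.on.error = FALSE)$value
  ## locate the peak of theta
  if (dtheta1(0) <= 0) {
    upeak <- 0
  } else {
    hi <- 2 / max(lam)
    while (dtheta1(hi) > 0) hi <- hi * 2
    upeak <- stats::uniroot(dtheta1, c(0, hi),
                            tol = .Machine$double.eps^0.75)$root
  }
  thmax <- theta1(upeak)
  M <- floor(thmax / pi)
  total <- 0
  lo <- 0
  ## ascending-branch crossings theta = m*pi, m = 1..M
  if (upeak > 0 && M >= 1) {
    for (m in seq_len(M)) {
      u <- stats::uniroot(function(v) theta1(v) - m * pi, c(lo, upeak),
                          tol = 1e-13)$root
      total <- total + chunk(lo, u)
      lo <- u
    }
  }
  ## descending-branch crossings theta = m*pi, m = M, M-1, ...
  desc_root <- function(target, from) {
    hi <- max(from, upeak, 1 / max(lam)) * 2 + 2
    while (theta1(hi) > target) hi <- hi * 2
    stats::uniroot(function(v) theta1(v) - target, c(from, hi),
                   tol = 1e-13)$root
  }
  terms <- numeric(0)
  m <- M
  repeat {
    u <- desc_root(m * pi, lo)
    tm <- chunk(lo, u)
    if (m >= 0) total <- total + tm else terms <- c(terms, tm)
    lo <- u
    m <- m - 1
    if (m < -1) {
      n <- length(terms)
      if (n >= 3 && abs(terms[n]) < 5e-14) {
        total <- total + sum(terms)
        terms <- NULL
        break
      }
      if (n >= n_alt) break
    }
  }
  if (!is.null(terms) && length(terms)) {
    ## direct sum of the pre-asymptotic head, Euler transform of the rest
    n0 <- min(20L, length(terms) - 1L)
    total <- total + sum(terms[seq_len(n0)])
    S <- cumsum(terms[(n0 + 1):length(terms)])
    while (length(S) > 1) S <- (S[-1] + S[-length(S)]) / 2
    total <- total + S
  }
  0.5 + total / pi
}

#' Liu moment-matching tail approximation
#'
#' Matches the first three cumulants of the mixture to a (possibly
#' noncentral) scaled chi-square and evaluates its upper tail; serves as the
#' fallback when characteristic-function inversion is unreliable.
#'
#' @inheritParams davies_pvalue
#' @return Upper-tail probability.
#' @export
liu_pvalue <- function(q, lambdas) {
  lam <- lambdas[lambdas > 0]
  if (!length(lam)) stop("all mixture weights are nonpositive")
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / sqrt(s2)
    delta <- 0
    l <- 1 / s2
  }
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta
  sigma_x <- sqrt(2) * a
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}
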