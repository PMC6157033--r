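test_that("intercept-only null model recovers mean and sample variance", {
  set.seed(21)
  x <- rnorm(25, 3, 2)
  m <- fit_null_lm(x, NULL)
  expect_equal(unname(m$beta), mean(x))
  expect_equal(m$sigma_e2, var(x))
  expect_lt(max(abs(m$P0 %*% m$C)), 1e-8)
  expect_error(fit_null_lm(2 * (1:20), cbind(1:20)), "exact linear")
})

test_that("mixture tail probabilities reproduce chi-square closed forms", {
  for (q in c(0.2, 1, 3.841459, 9, 14)) {
    d1 <- davies_pvalue(q, 1)
    expect_equal(d1$pvalue, pchisq(q, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
    expect_identical(d1$method_used, "davies")
    d2 <- davies_pvalue(q, c(1, 1))
    expect_equal(d2$pvalue, exp(-q / 2), tolerance = 1e-9)
  }
  expect_equal(davies_pvalue(3.841459, 1)$pvalue, 0.05, tolerance = 1e-6)
  expect_equal(davies_pvalue(5.991465, c(1, 1))$pvalue, 0.05,
               tolerance = 1e-6)
  expect_error(davies_pvalue(1, c(-1, 0)), "nonpositive")
})

test_that("unequal-weight mixtures match an independent convolution oracle", {
  # P(2A + B > q), A,B ~ chi2_1, by conditioning on A
  oracle <- function(q) {
    stats::integrate(function(a) dchisq(a, 1) *
                       pchisq(q - 2 * a, 1, lower.tail = FALSE),
                     0, q / 2, rel.tol = 1e-12)$value +
      pchisq(q / 2, 1, lower.tail = FALSE)
  }
  for (q in c(2, 5, 10, 20)) {
    got <- davies_pvalue(q, c(2, 1))
    expect_equal(got$pvalue, oracle(q), tolerance = 1e-8)
  }
  # Liu fallback is a usable approximation in the same regime
  expect_lt(abs(liu_pvalue(10, c(2, 1)) - oracle(10)), 2e-3)
})

test_that("single-CpG score test equals the closed-form partial-correlation test", {
  set.seed(22)
  n <- 90
  C <- cbind(rnorm(n), rbinom(n, 1, 0.4))
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n)
  null <- fit_null_lm(x, C)
  qf <- vc_score_test(null, x, matrix(y))
  r2 <- cor(resid(lm(x ~ C)), resid(lm(y ~ C)))^2
  stat <- (n - null$r) * r2
  expect_equal(qf$Q / qf$eigenvalues[1], stat, tolerance = 1e-8)
  expect_equal(qf$pvalue, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("eigenvalue sum matches trace(P0 K) and p is scale invariant", {
  set.seed(23)
  n <- 60; p <- 8
  Y <- matrix(rnorm(n * p), n, p)
  C <- cbind(rnorm(n))
  x <- rnorm(n)
  null <- fit_null_lm(x, C)
  qf <- vc_score_test(null, x, Y)
  Z <- scale(Y, scale = FALSE)
  expect_equal(sum(qf$eigenvalues), sum(diag(null$P0 %*% tcrossprod(Z))),
               tolerance = 1e-6)
  # multiplying x by a constant leaves the p-value unchanged
  null2 <- fit_null_lm(5 * x, C)
  qf2 <- vc_score_test(null2, 5 * x, Y)
  expect_equal(qf2$pvalue, qf$pvalue, tolerance = 1e-8)
  # same for the family model
  kin <- kinship_from_pedigree(random_pedigree(4, 6, seed = 9))
  xk <- rnorm(10)
  Yk <- matrix(rnorm(10 * 3), 10, 3)
  n1 <- fit_null_lmm(xk, NULL, kin)
  n2 <- fit_null_lmm(-3 * xk, NULL, kin)
  expect_equal(vc_score_test(n2, -3 * xk, Yk)$pvalue,
               vc_score_test(n1, xk, Yk)$pvalue, tolerance = 1e-6)
})

test_that("kinship LMM collapses to the linear model when 2*Phi = I", {
  set.seed(24)
  n <- 50
  C <- cbind(rnorm(n))
  x <- rnorm(n) + 0.5 * C[, 1]
  kinI <- diag(0.5, n)
  dimnames(kinI) <- list(paste0("s", 1:n), paste0("s", 1:n))
  lm0 <- fit_null_lm(x, C)
  lmm0 <- fit_null_lmm(x, C, kinI)
  expect_lt(max(abs(lmm0$P0 - lm0$P0)), 1e-6)
  Y <- matrix(rnorm(n * 6), n, 6)
  expect_equal(vc_score_test(lmm0, x, Y)$pvalue,
               vc_score_test(lm0, x, Y)$pvalue, tolerance = 1e-6)
})

test_that("REML recovers variance components and detects the zero boundary", {
  cfg <- sim_config(n_families = 40, family_structure = "three_gen",
                    n_genes = 1, cpgs_per_gene = 2, seed = 31)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_from_pedigree(ped)
  keig <- eigen(2 * kin, symmetric = TRUE)
  A2h <- keig$vectors %*% (t(keig$vectors) * sqrt(pmax(keig$values, 0)))
  n <- nrow(ped)
  set.seed(32)
  est <- replicate(40, {
    x <- as.numeric(A2h %*% rnorm(n)) + rnorm(n)   # sigma_g2 = sigma_e2 = 1
    m <- fit_null_lmm(x, NULL, kin, kin_eigen = keig, compute_P0 = FALSE)
    m$sigma_g2 / (m$sigma_g2 + m$sigma_e2)
  })
  expect_equal(mean(est), 0.5, tolerance = 0.05)
  # truth sigma_g2 = 0: estimates pile up at the lower boundary
  set.seed(33)
  at_zero <- replicate(30, {
    m <- fit_null_lmm(rnorm(n), NULL, kin, kin_eigen = keig,
                      compute_P0 = FALSE)
    m$sigma_g2 / (m$sigma_g2 + m$sigma_e2) < 0.02
  })
  expect_gt(mean(at_zero), 0.5)
  kbad <- diag(0.5, 4)
  kbad[1, 2] <- kbad[2, 1] <- 0.9   # 2*Phi has a negative eigenvalue
  expect_error(fit_null_lmm(rnorm(4), NULL, kbad), "positive semi-definite")
})

test_that("permuted-trait Q statistics follow the fitted eigen-mixture", {
  set.seed(25)
  n <- 80; p <- 6
  Y <- matrix(rnorm(n * p), n, p)
  x <- rnorm(n)
  null <- fit_null_lm(x, NULL)
  qf <- vc_score_test(null, x, Y)
  Z <- scale(Y, scale = FALSE)
  qs <- replicate(400, {
    xp <- sample(x)
    nullp <- fit_null_lm(xp, NULL)
    sum(crossprod(Z, nullp$P0 %*% xp)^2)
  })
  # theoretical quantiles by sampling the mixture
  ref <- colSums(qf$eigenvalues * matrix(rchisq(400 * qf$n_eigs, 1),
                                         qf$n_eigs))
  expect_gt(cor(sort(qs), sort(ref)), 0.98)
})

test_that("degenerate blocks are flagged rather than tested", {
  set.seed(26)
  x <- rnorm(30)
  null <- fit_null_lm(x, NULL)
  expect_warning(out <- vc_score_test(null, x, matrix(0.5, 30, 2)),
                 "constant")
  expect_equal(out$pvalue, 1)
  expect_error(vc_score_test(null, x, matrix(numeric(0), 30, 0)), "empty")
})
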