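test_that("a CpG identical to the trait is detected with overwhelming evidence", {
  set.seed(41)
  x <- rnorm(50)
  res <- cpg_lm_test(x, NULL, x, cpg_id = "cg_self")
  expect_lt(res$pvalue, 1e-30)
  expect_identical(res$method, "univariate_lm")
})

test_that("the vectorized scan agrees with single-CpG fits and lm()", {
  set.seed(42)
  n <- 40
  C <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("cg", 1:6)))
  x <- rnorm(n) + 0.4 * Y[, 3]
  many <- cpg_lm_test_many(x, C, Y)
  for (j in c(1, 3, 6)) {
    single <- cpg_lm_test(x, C, Y[, j], cpg_id = colnames(Y)[j])
    expect_equal(many$pvalue[j], single$pvalue, tolerance = 1e-12)
    p_lm <- summary(lm(x ~ C + Y[, j]))$coefficients[4, 4]
    expect_equal(single$pvalue, p_lm, tolerance = 1e-12)
  }
})

test_that("Wald LM and score VC tests agree asymptotically at p = 1", {
  set.seed(43)
  n <- 500
  C <- cbind(rnorm(n))
  x <- rnorm(n)
  y <- rnorm(n) + 0.05 * x
  p_lm <- cpg_lm_test(x, C, y)$pvalue
  p_vc <- vc_score_test(fit_null_lm(x, C), x, matrix(y))$pvalue
  expect_lt(abs(p_lm - p_vc), 2e-3)   # Wald and score differ at O(1/n)
})

test_that("p-values are invariant to affine rescaling of the CpG", {
  set.seed(44)
  n <- 60
  x <- rnorm(n)
  y <- rnorm(n)
  p0 <- cpg_lm_test(x, NULL, y)$pvalue
  expect_equal(cpg_lm_test(x, NULL, 10 * y - 3)$pvalue, p0,
               tolerance = 1e-12)
  kin <- diag(0.5, n)
  p1 <- cpg_lmm_test(x, NULL, y, kin)$pvalue
  expect_equal(cpg_lmm_test(x, NULL, -2 * y + 1, kin)$pvalue, p1,
               tolerance = 1e-8)
})

test_that("LMM Wald test collapses to the linear model when 2*Phi = I", {
  set.seed(45)
  n <- 120
  C <- cbind(rnorm(n))
  y <- rnorm(n)
  x <- rnorm(n) + 0.2 * y
  p_lm <- cpg_lm_test(x, C, y)$pvalue
  p_lmm <- cpg_lmm_test(x, C, y, diag(0.5, n))$pvalue
  expect_equal(p_lmm, p_lm, tolerance = 1e-8)
})

test_that("fast approximation reuses null components yet tracks the exact fit", {
  cfg <- sim_config(n_families = 30, family_structure = "nuclear2",
                    n_genes = 1, cpgs_per_gene = 4, meth_h2 = 0.3,
                    pheno_h2 = 0.4, n_latent = 0, seed = 46)
  co <- simulate_cohort(cfg)
  x <- prepare_trait(co$phenotypes, "tg")
  keig <- eigen(2 * co$kinship, symmetric = TRUE)
  nullm <- fit_null_lmm(x, NULL, co$kinship, kin_eigen = keig,
                        compute_P0 = FALSE)
  y <- co$meth[, 1]
  exact <- cpg_lmm_test(x, NULL, y, co$kinship, kin_eigen = keig)
  fast <- cpg_lmm_test(x, NULL, y, co$kinship, fast = TRUE, null = nullm)
  expect_equal(fast$pvalue, exact$pvalue, tolerance = 0.05)
  expect_error(cpg_lmm_test(x, NULL, y, co$kinship, fast = TRUE),
               "requires a kinship null model")
})

test_that("constant CpGs warn and return p = 1", {
  x <- rnorm(20)
  expect_warning(res <- cpg_lm_test(x, NULL, rep(0.3, 20)), "constant")
  expect_equal(res$pvalue, 1)
})
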