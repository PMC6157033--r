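test_that("probe sampling is deterministic, exhaustive at the limit, seed-sensitive", {
  set.seed(1)
  meth <- methylation_matrix(matrix(runif(20 * 10000), 20, 10000),
                             sprintf("s%02d", 1:20),
                             sprintf("cg%05d", 1:10000))
  expect_identical(sample_probes(meth, 100, seed = 3),
                   sample_probes(meth, 100, seed = 3))
  expect_false(identical(sample_probes(meth, 100, seed = 3),
                         sample_probes(meth, 100, seed = 4)))
  expect_setequal(sample_probes(meth, 10000, seed = 1), colnames(meth))
  expect_error(sample_probes(meth, 10001, seed = 1), "available")
})

test_that("autosome restriction honors chromosome labels when present", {
  meth <- methylation_matrix(matrix(runif(4 * 6), 4, 6),
                             paste0("s", 1:4), paste0("cg", 1:6))
  annot <- data.frame(cpg_id = paste0("cg", 1:6),
                      chrom = c("chr1", "chrX", "chr2", "chrY", "chr3",
                                "chr1"),
                      pos = 1:6)
  got <- sample_probes(meth, 4, seed = 1, annot = annot)
  expect_setequal(got, c("cg1", "cg3", "cg5", "cg6"))
})

test_that("PCs capture exact low-rank structure with orthogonal scores", {
  set.seed(5)
  n <- 30
  f <- rnorm(n)
  load <- runif(50, 0.5, 1)
  X <- plogis(outer(f, load))      # rank-1 latent structure on logit scale
  meth <- methylation_matrix(X, paste0("s", 1:n), paste0("cg", 1:50))
  pcs <- compute_pcs(beta_logit(meth), colnames(meth), k = 2)
  expect_gt(pcs$explained_variance[1], 0.999)
  expect_lt(max(abs(pcs$scores[, 2])), 1e-6)
  expect_lt(abs(crossprod(pcs$scores)[1, 2]), 1e-8)
  expect_error(compute_pcs(methylation_matrix(matrix(0.5, 10, 5),
                                              paste0("s", 1:10),
                                              paste0("cg", 1:5)),
                           paste0("cg", 1:5), k = 2),
               "constant")
})

test_that("PCs are invariant to per-probe constant shifts (centering)", {
  set.seed(6)
  X <- matrix(rnorm(40 * 30), 40, 30)
  m1 <- methylation_matrix(plogis(X), paste0("s", 1:40), paste0("cg", 1:30))
  sc1 <- compute_pcs(beta_logit(m1), colnames(m1), k = 3)$scores
  shifted <- beta_logit(m1)
  shifted <- sweep(shifted, 2, runif(30, -1, 1), `+`)
  m2 <- methylation_matrix(shifted, rownames(m1), colnames(m1),
                           scale = "logit")
  sc2 <- compute_pcs(m2, colnames(m2), k = 3)$scores
  expect_equal(sc1, sc2, tolerance = 1e-8)
})

test_that("top PCs recover strong simulated latent factors", {
  co <- simulate_cohort(sim_config(n_families = 50,
                                   family_structure = "nuclear2",
                                   n_genes = 50, cpgs_per_gene = 20,
                                   n_latent = 2, latent_sd = 1,
                                   meth_h2 = 0, pheno_h2 = 0, seed = 8))
  probes <- sample_probes(co$meth, 1000, seed = 2)
  pcs <- compute_pcs(co$meth, probes, k = 4)
  for (j in 1:2)
    expect_gt(max(abs(cor(co$truth$latent_factors[, j], pcs$scores))), 0.9)
})
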