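test_that("pedigree presets give the documented family sizes", {
  ped1 <- simulate_pedigree(sim_config(n_families = 1,
                                       family_structure = "trio", seed = 1))
  expect_equal(nrow(ped1), 3)
  kid <- ped1[3, ]
  expect_true(kid$father_id != "0" && kid$mother_id != "0")
  ped2 <- simulate_pedigree(sim_config(n_families = 60,
                                       family_structure = "nuclear2",
                                       seed = 1))
  expect_equal(nrow(ped2), 240)
  ped3 <- simulate_pedigree(sim_config(n_families = 2,
                                       family_structure = "three_gen",
                                       seed = 1))
  expect_equal(nrow(ped3), 14)
  expect_error(sim_config(family_structure = "clan"), "unknown")
})

test_that("cohorts are byte-identical under a fixed seed", {
  cfg <- sim_config(n_families = 10, family_structure = "nuclear2",
                    n_genes = 3, cpgs_per_gene = 5, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("beta values stay strictly inside (0, 1) and CpGs sit near their gene", {
  co <- simulate_cohort(sim_config(n_families = 5, n_genes = 4,
                                   cpgs_per_gene = c(5, 15), seed = 7))
  expect_true(all(co$meth > 0 & co$meth < 1))
  expect_equal(nrow(co$annot), ncol(co$meth))
  asg <- assign_cpgs_to_genes(co$annot, co$genes, flank = 20000)
  expect_setequal(unlist(asg), co$annot$cpg_id)  # all CpGs within the flanks
})

test_that("within-block correlation follows the exchangeable construction", {
  # independent case: average absolute off-diagonal correlation is small
  co0 <- simulate_cohort(sim_config(n_families = 125,
                                    family_structure = "nuclear2",
                                    n_genes = 3, cpgs_per_gene = 10,
                                    block_rho = 0, meth_h2 = 0,
                                    n_latent = 0, seed = 55))
  cc <- cor(co0$meth[, 1:10])
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)
  # block_rho = 0.5: mean latent-scale within-block correlation near 0.5
  cfg <- sim_config(n_families = 500, family_structure = "nuclear2",
                    n_genes = 2, cpgs_per_gene = 10, block_rho = 0.5,
                    meth_h2 = 0, n_latent = 0, seed = 56)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_from_pedigree(ped)
  ms <- simulate_methylation(ped, kin, cfg)
  cl <- cor(ms$latent_meth[, 1:10])
  expect_gt(mean(cl[upper.tri(cl)]), 0.45)
  expect_lt(mean(cl[upper.tri(cl)]), 0.55)
})

test_that("null per-CpG regressions of the lipid change are calibrated", {
  co <- simulate_cohort(sim_config(n_families = 100,
                                   family_structure = "nuclear2",
                                   n_genes = 50, cpgs_per_gene = 20,
                                   n_latent = 0, pheno_h2 = 0,
                                   meth_h2 = 0, seed = 57))
  x <- prepare_trait(co$phenotypes, "tg")
  pv <- cpg_lm_test_many(x, NULL, co$meth)$pvalue
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.02)   # 1000 null CpGs
})

test_that("config validation guards impossible variance splits and genes", {
  expect_error(sim_config(meth_h2 = 0.6, block_rho = 0.5), "negative")
  cfg <- sim_config(n_families = 4, n_genes = 2, cpgs_per_gene = 4,
                    effect_blocks = list(list(gene_id = "nope", effect = 1,
                                              prop_causal = 0.5)),
                    seed = 3)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_from_pedigree(ped)
  ms <- simulate_methylation(ped, kin, cfg)
  expect_error(simulate_phenotypes(ped, kin, ms, cfg), "unknown gene")
})
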