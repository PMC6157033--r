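test_that("kinship recursion reproduces textbook coefficients", {
  kin <- kinship_from_pedigree(make_nuclear4())
  expect_equal(kin["dad", "c1"], 0.25)   # parent-offspring
  expect_equal(kin["c1", "c2"], 0.25)    # full siblings
  expect_equal(kin["dad", "mom"], 0)     # unrelated founders
  expect_equal(diag(kin), c(dad = 0.5, mom = 0.5, c1 = 0.5, c2 = 0.5))
  # half siblings: shared father, different mothers
  half <- data.frame(family_id = "f",
                     individual_id = c("dad", "m1", "m2", "h1", "h2"),
                     father_id = c("0", "0", "0", "dad", "dad"),
                     mother_id = c("0", "0", "0", "m1", "m2"),
                     sex = c("1", "2", "2", "1", "1"))
  expect_equal(kinship_from_pedigree(half)["h1", "h2"], 0.125)
  # inbred child of full sibs: phi_ii = 0.5 + 0.5 * 0.25
  inb <- rbind(make_nuclear4(),
               data.frame(family_id = "f1", individual_id = "x",
                          father_id = "c1", mother_id = "c2", sex = "1"))
  expect_equal(kinship_from_pedigree(inb)["x", "x"], 0.625)
})

test_that("kinship matrices are symmetric and 2*Phi is PSD on random pedigrees", {
  for (seed in 1:5) {
    ped <- random_pedigree(n_founders = 4, n_children = 8, seed = seed)
    kin <- kinship_from_pedigree(ped)
    expect_equal(kin, t(kin))
    expect_true(all(diag(kin) >= 0.5))
    ev <- eigen(2 * kin, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("greedy unrelated selection matches brute-force optimum on small families", {
  kin_trio <- kinship_from_pedigree(make_trio())
  sel <- select_unrelated(kin_trio, 0.05)
  expect_identical(sel, c("dad", "mom"))   # child has degree 2, removed first
  kin4 <- kinship_from_pedigree(make_nuclear4())
  sel4 <- select_unrelated(kin4, 0.05)
  expect_identical(sel4, c("dad", "mom"))
  expect_equal(length(sel4),
               max_independent_set_size(kin4 >= 0.05 & !diag(4)))
  # all-founder cohort: nobody removed
  founders <- data.frame(family_id = "f", individual_id = letters[1:5],
                         father_id = "0", mother_id = "0", sex = "1")
  kinf <- kinship_from_pedigree(founders)
  expect_identical(select_unrelated(kinf, 0.05), letters[1:5])
})

test_that("selected subsets are independent and maximal on random pedigrees", {
  thr <- 0.0221
  for (seed in 6:10) {
    ped <- random_pedigree(4, 7, seed)
    kin <- kinship_from_pedigree(ped)
    keep <- select_unrelated(kin, thr)
    expect_true(is_independent(kin, keep, thr))
    # maximality: no removed individual can be re-added
    for (out in setdiff(rownames(kin), keep))
      expect_false(is_independent(kin, c(keep, out), thr))
  }
})

test_that("selection is invariant to row permutation up to the tie-break", {
  ped <- random_pedigree(4, 7, seed = 11)
  kin <- kinship_from_pedigree(ped)
  perm <- sample(nrow(kin))
  keep1 <- select_unrelated(kin, 0.0221)
  keep2 <- select_unrelated(kin[perm, perm], 0.0221)
  expect_setequal(keep1, keep2)
  expect_error(select_unrelated(matrix(c(0.5, 0.1, 0.3, 0.5), 2, 2), 0.05),
               "symmetric")
  expect_error(select_unrelated(kin, 0), "> 0")
})
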