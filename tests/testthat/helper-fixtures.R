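# in-code fixtures shared across test files

make_trio <- function() {
  data.frame(family_id = "f1",
             individual_id = c("dad", "mom", "kid"),
             father_id = c("0", "0", "dad"),
             mother_id = c("0", "0", "mom"),
             sex = c("1", "2", "1"), stringsAsFactors = FALSE)
}

make_nuclear4 <- function() {
  data.frame(family_id = "f1",
             individual_id = c("dad", "mom", "c1", "c2"),
             father_id = c("0", "0", "dad", "dad"),
             mother_id = c("0", "0", "mom", "mom"),
             sex = c("1", "2", "1", "2"), stringsAsFactors = FALSE)
}

# random acyclic pedigree: founders plus children of random earlier couples
random_pedigree <- function(n_founders, n_children, seed) {
  set.seed(seed)
  ids <- sprintf("i%02d", seq_len(n_founders + n_children))
  fa <- mo <- rep("0", n_founders + n_children)
  sex <- c(rep(c("1", "2"), length.out = n_founders),
           sample(c("1", "2"), n_children, replace = TRUE))
  for (k in seq_len(n_children)) {
    i <- n_founders + k
    males <- which(sex[seq_len(i - 1)] == "1")
    females <- which(sex[seq_len(i - 1)] == "2")
    fa[i] <- ids[males[sample.int(length(males), 1)]]
    mo[i] <- ids[females[sample.int(length(females), 1)]]
  }
  data.frame(family_id = "f1", individual_id = ids, father_id = fa,
             mother_id = mo, sex = sex, stringsAsFactors = FALSE)
}

# brute-force maximum independent set size over all vertex subsets
max_independent_set_size <- function(adj) {
  n <- nrow(adj)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    keep <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(keep) <= best) next
    if (length(keep) < 2 ||
        all(!adj[keep, keep][upper.tri(diag(length(keep)))]))
      best <- length(keep)
  }
  best
}

# independence check for a retained subset
is_independent <- function(kin, keep, threshold) {
  sub <- kin[keep, keep, drop = FALSE]
  all(sub[upper.tri(sub)] < threshold)
}
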