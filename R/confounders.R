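#' Sample probes for confounder principal components
#'
#' Uniform sampling without replacement of CpG probes, deterministic given
#' the seed.  When an annotation is supplied the sample is restricted to
#' autosomal probes (chromosome labels other than X, Y and MT variants);
#' otherwise all supplied probes are eligible.
#'
#' @param meth Methylation matrix (samples x CpGs).
#' @param n_probes Number of probes to draw (default 2000).
#' @param seed Integer seed.
#' @param annot Optional CpG annotation used to drop sex chromosomes.
#' @return Character vector of sampled probe ids.
#' @export
sample_probes <- function(meth, n_probes = 2000, seed = 1, annot = NULL) {
  pool <- colnames(meth)
  if (!is.null(annot)) {
    sex <- c("chrX", "chrY", "chrM", "chrMT", "X", "Y", "MT", "23", "24")
    auto <- annot$cpg_id[!(annot$chrom %in% sex)]
    pool <- pool[pool %in% auto]
  }
  if (n_probes > length(pool))
    stop(sprintf("requested %d probes but only %d available",
                 n_probes, length(pool)))
  set.seed(seed)
  sort(sample(pool, n_probes))
}

#' Methylation-derived confounder principal components
#'
#' Column-centers the `n x m` probe submatrix and takes the leading `k` left
#' singular vectors scaled by their singular values, giving orthogonal PC
#' scores capturing cell-composition and batch-like structure.  Sign
#' convention: within each component the largest-magnitude probe loading is
#' made positive, for cross-platform determinism.
#'
#' @param meth Methylation matrix (samples x CpGs).
#' @param probe_ids Probe ids to use (e.g. from [sample_probes()]).
#' @param k Number of components (default 4).
#' @return List of class `"confounder_pcs"` with `scores`
#'   (`n x k`, columns `PC1..PCk`), `probe_ids_used`, and
#'   `explained_variance` (proportion of total probe variance per component).
#' @export
compute_pcs <- function(meth, probe_ids, k = 4) {
  X <- meth[, probe_ids, drop = FALSE]
  if (k > min(nrow(X) - 1, ncol(X)))
    stop("k exceeds min(n_samples - 1, n_probes)")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  if (tot < 1e-12) stop("probe submatrix is constant; no principal components")
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k, k), 2, flip, `*`)
  dimnames(scores) <- list(rownames(meth), paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 probe_ids_used = probe_ids,
                 explained_variance = sv$d[seq_len(k)]^2 / tot),
            class = "confounder_pcs")
}
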