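#' Pedigree kinship matrix
#'
#' Computes pairwise kinship coefficients \eqn{\phi_{ij}} by the classical
#' recursion over a topologically sorted pedigree: founders are mutually
#' unrelated with \eqn{\phi_{ii} = 1/2}; for an individual `i` with parents
#' `f` and `m`, \eqn{\phi_{ii} = 1/2 + \phi_{fm}/2} and, for any previously
#' processed `j`, \eqn{\phi_{ij} = (\phi_{fj} + \phi_{mj})/2} (a missing
#' parent contributes 0).  The doubled matrix \eqn{2\Phi} is the additive
#' relationship matrix used by the kinship linear mixed models.
#'
#' @param ped Pedigree data frame (see [read_pedigree()]).
#' @return Symmetric kinship matrix ordered as the pedigree rows, with
#'   individual ids as dimnames.
#' @export
kinship_from_pedigree <- function(ped) {
  topo <- validate_pedigree(ped)
  ids <- ped$individual_id
  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- ids
  fa <- ifelse(ped$father_id == "0", NA_integer_, idx[ped$father_id])
  mo <- ifelse(ped$mother_id == "0", NA_integer_, idx[ped$mother_id])
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- integer(0)
  for (id in topo) {
    i <- idx[[id]]
    f <- fa[i]; m <- mo[i]
    if (length(done)) {
      row_f <- if (is.na(f)) 0 else phi[f, done]
      row_m <- if (is.na(m)) 0 else phi[m, done]
      phi[i, done] <- phi[done, i] <- 0.5 * (row_f + row_m)
    }
    phi_fm <- if (is.na(f) || is.na(m)) 0 else phi[f, m]
    phi[i, i] <- 0.5 + 0.5 * phi_fm
    done <- c(done, i)
  }
  phi
}

#' Greedy selection of a maximal unrelated subset
#'
#' Builds the relatedness graph with an edge between `i` and `j` whenever
#' \eqn{\phi_{ij} \ge} `threshold`, then repeatedly removes the vertex with
#' the largest current degree (ties broken by lexicographically smallest
#' sample id) until no edges remain.  A final pass re-admits, in original
#' row order, any removed individual no longer adjacent to a survivor, so
#' the returned set is maximal: no removed individual could be added back
#' without violating the kinship constraint.
#'
#' The default threshold 0.0221 (about \eqn{2^{-5.5}}, below half first
#' cousins) splits any pair sharing a pedigree ancestor, so within-family
#' relatives are never retained together.
#'
#' @param kin Symmetric kinship matrix with sample ids as dimnames.
#' @param threshold Kinship cutoff defining relatedness (> 0).
#' @return Character vector of retained sample ids, in the input order.
#' @export
select_unrelated <- function(kin, threshold = 0.0221) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (max(abs(kin - t(kin))) > 1e-8) stop("kinship matrix is not symmetric")
  ids <- rownames(kin)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(kin)))
  adj <- kin >= threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, nrow(kin))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    cand <- which(deg == max(deg))
    drop <- cand[order(ids[cand])][1]
    alive[drop] <- FALSE
  }
  ## maximality pass: re-admit anyone with no surviving relative
  for (i in which(!alive)) {
    if (!any(adj[i, alive])) alive[i] <- TRUE
  }
  ids[alive]
}
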