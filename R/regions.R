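#' Assign CpG sites to gene regions with flanking windows
#'
#' A CpG at 1-based position `p` is assigned to a gene with 0-based
#' half-open interval `[s, e)` on the same chromosome iff
#' `s - flank < p <= e + flank`.  This is the single point where the two
#' coordinate conventions meet.  A CpG inside several overlapping gene
#' windows is assigned to each of them; CpGs matching no gene are dropped
#' (only annotated sites are tested downstream).
#'
#' @param annot CpG annotation data frame (`cpg_id`, `chrom`, `pos`).
#' @param genes Gene-region data frame (`gene_id`, `chrom`, `start`, `end`).
#' @param flank Flanking window in bp on each side (default 20000).
#' @return Named list mapping `gene_id` to its CpG ids ordered by genomic
#'   position (ties by CpG id); genes with no CpGs are omitted.
#' @export
assign_cpgs_to_genes <- function(annot, genes, flank = 20000) {
  validate_gene_regions(genes)
  by_chrom <- split(annot, annot$chrom)
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (g in seq_len(nrow(genes))) {
    a <- by_chrom[[genes$chrom[g]]]
    if (is.null(a)) next
    hit <- a$pos > genes$start[g] - flank & a$pos <= genes$end[g] + flank
    if (!any(hit)) next
    a <- a[hit, , drop = FALSE]
    out[[g]] <- a$cpg_id[order(a$pos, a$cpg_id)]
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Split an oversized gene CpG set into blocks of bounded size
#'
#' A gene with `p` position-sorted CpGs is cut into
#' `k = ceiling(p / max_block_size)` contiguous chunks of as-equal-as-possible
#' sizes (the first `p %% k` chunks get one extra site).  For `k = 1` the
#' block keeps the gene id; otherwise blocks are suffixed `_1 ... _k`.
#'
#' @param gene_id Gene identifier.
#' @param cpg_ids Position-ordered CpG ids belonging to the gene.
#' @param max_block_size Maximum CpGs per block (default 130).
#' @return List of character vectors, named by block id; their concatenation
#'   equals `cpg_ids`.
#' @export
split_blocks <- function(gene_id, cpg_ids, max_block_size = 130) {
  p <- length(cpg_ids)
  if (p == 0) stop("cannot split an empty CpG set")
  k <- ceiling(p / max_block_size)
  base <- p %/% k
  sizes <- rep(base, k)
  extra <- p %% k
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  blocks <- lapply(seq_len(k), function(i) cpg_ids[starts[i]:ends[i]])
  names(blocks) <- if (k == 1) gene_id else paste0(gene_id, "_", seq_len(k))
  blocks
}

#' Build the full block table from annotation and gene regions
#'
#' Runs [assign_cpgs_to_genes()] followed by [split_blocks()] on every gene
#' and returns a flat long-format table, one row per (block, CpG).
#'
#' @inheritParams assign_cpgs_to_genes
#' @inheritParams split_blocks
#' @return `data.frame` with columns `block_id`, `gene_id`, `chrom`,
#'   `cpg_id`, `rank` (1-based position rank within the block).
#' @export
build_blocks <- function(annot, genes, flank = 20000, max_block_size = 130) {
  assign <- assign_cpgs_to_genes(annot, genes, flank = flank)
  chrom_of <- genes$chrom
  names(chrom_of) <- genes$gene_id
  rows <- lapply(names(assign), function(g) {
    blocks <- split_blocks(g, assign[[g]], max_block_size = max_block_size)
    do.call(rbind, lapply(names(blocks), function(b) {
      data.frame(block_id = b, gene_id = g, chrom = unname(chrom_of[g]),
                 cpg_id = blocks[[b]],
                 rank = seq_along(blocks[[b]]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(block_id = character(0), gene_id = character(0),
                      chrom = character(0), cpg_id = character(0),
                      rank = integer(0))
  rownames(out) <- NULL
  out
}
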