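#' Logit transform of methylation beta values
#'
#' Maps beta values (methylation proportions) to M-values,
#' `log(b / (1 - b))`, after clipping to `[eps, 1 - eps]` so boundary values
#' stay finite.  Interior values are perturbed negligibly.
#'
#' @param b Numeric vector or matrix of beta values in `[0, 1]`.
#' @param eps Clipping bound (default `1e-6`).
#' @return Object of the same shape on the logit (M-value) scale.
#' @export
beta_logit <- function(b, eps = 1e-6) {
  b <- pmin(pmax(b, eps), 1 - eps)
  log(b / (1 - b))
}

#' Construct a methylation matrix
#'
#' In memory methylation is always oriented samples x CpGs (each row is one
#' subject's profile), whatever the on-disk orientation.  The measurement
#' scale (`"beta"` for proportions in `[0, 1]`, `"logit"` for M-values) is
#' carried as the `meth_scale` attribute.
#'
#' @param values Numeric matrix, samples in rows, CpGs in columns.
#' @param sample_ids,cpg_ids Unique identifier vectors matching the dimensions.
#' @param scale `"beta"` or `"logit"`.
#' @return A validated numeric matrix with dimnames and a `meth_scale`
#'   attribute.
#' @export
methylation_matrix <- function(values, sample_ids = rownames(values),
                               cpg_ids = colnames(values),
                               scale = c("beta", "logit")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(cpg_ids))
    stop("sample and CpG identifiers are required")
  sample_ids <- as.character(sample_ids)
  cpg_ids <- as.character(cpg_ids)
  if (length(sample_ids) != nrow(values) || length(cpg_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(cpg_ids)) stop("duplicate CpG ids")
  if (!is.numeric(values)) stop("methylation values must be numeric")
  if (anyNA(values)) stop("missing methylation values are not supported")
  if (!all(is.finite(values))) stop("non-finite methylation values")
  if (scale == "beta" && (any(values < 0) || any(values > 1)))
    stop("beta values must lie in [0, 1]")
  dimnames(values) <- list(sample_ids, cpg_ids)
  attr(values, "meth_scale") <- scale
  values
}

#' Read a methylation matrix from TSV
#'
#' On disk the matrix is CpG x sample (first column `cpg_id`, header row of
#' sample ids), matching the usual array-export convention; the returned
#' matrix is transposed to samples x CpGs.
#'
#' @param path Path to a TSV file.
#' @param scale `"beta"` to keep proportions, `"logit"` to transform with
#'   [beta_logit()] (clipping at `1e-6`).
#' @return A methylation matrix (see [methylation_matrix()]).
#' @export
read_methylation <- function(path, scale = c("beta", "logit")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2) stop("methylation file needs a cpg_id column plus samples")
  cpg_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    i <- (bad - 1) %% nrow(body) + 1
    j <- (bad - 1) %/% nrow(body) + 1
    stop(sprintf("non-numeric methylation value at CpG '%s', sample '%s'",
                 cpg_ids[i], sample_ids[j]))
  }
  m <- matrix(vals, nrow = nrow(body), ncol = ncol(body))
  if (any(m < 0) || any(m > 1))
    stop("beta value outside [0, 1] in methylation file")
  if (scale == "logit") m <- beta_logit(m)
  methylation_matrix(t(m), sample_ids, cpg_ids, scale = scale)
}

#' Write a methylation matrix to TSV (CpG x sample orientation)
#'
#' @param meth Methylation matrix (samples x CpGs in memory).
#' @param path Output path.
#' @export
write_methylation <- function(meth, path) {
  df <- data.frame(cpg_id = colnames(meth),
                   t(format_num(meth)), check.names = FALSE)
  colnames(df)[-1] <- rownames(meth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## 17-significant-digit formatting so numeric TSVs round-trip losslessly
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Read a PLINK-style pedigree file
#'
#' Whitespace-delimited text with at least five columns
#' (family id, individual id, father id, mother id, sex); `"0"` marks a
#' missing parent.  Validation requires unique individual ids, every
#' non-missing parent present in the file, and an acyclic parentage graph.
#'
#' @param path Path to the pedigree file (no header).
#' @return A `data.frame` with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 5) stop("pedigree file needs at least 5 columns")
  ped <- data.frame(family_id = df[[1]], individual_id = df[[2]],
                    father_id = df[[3]], mother_id = df[[4]],
                    sex = df[[5]], stringsAsFactors = FALSE)
  validate_pedigree(ped)
  ped
}

#' Write a pedigree in PLINK FAM-style layout
#' @param ped Pedigree data frame.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[, c("family_id", "individual_id", "father_id",
                             "mother_id", "sex")],
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a pedigree and return its topological order
#'
#' Checks id uniqueness, parent presence and acyclicity (no individual is its
#' own ancestor).  The returned order lists parents before children.
#'
#' @param ped Pedigree data frame (see [read_pedigree()]).
#' @return Character vector of individual ids in topological order,
#'   invisibly for the validation use.
#' @export
validate_pedigree <- function(ped) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  if (!all(need %in% colnames(ped))) stop("pedigree columns missing")
  ids <- ped$individual_id
  if (anyDuplicated(ids)) stop("duplicate individual ids in pedigree")
  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    miss <- ref != "0" & !(ref %in% ids)
    if (any(miss))
      stop(sprintf("parent id '%s' referenced but absent", ref[miss][1]))
  }
  ## Kahn's algorithm on parent -> child edges
  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- ids
  parents <- cbind(ifelse(ped$father_id == "0", NA, idx[ped$father_id]),
                   ifelse(ped$mother_id == "0", NA, idx[ped$mother_id]))
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", n)
  for (i in idx) {
    for (p in parents[i, ]) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- idx[indeg == 0]
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) stop("cycle in pedigree parentage")
  invisible(ids[order])
}

#' Read gene regions from a BED4 file
#'
#' BED coordinates are 0-based half-open and are preserved as such
#' internally; the single conversion point to the 1-based CpG coordinates is
#' [assign_cpgs_to_genes()].
#'
#' @param path Path to a BED4 file (chrom, start, end, name).
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`, in
#'   file order.
#' @export
read_gene_regions <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id"),
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  genes <- df[, c("gene_id", "chrom", "start", "end")]
  validate_gene_regions(genes)
  genes
}

validate_gene_regions <- function(genes) {
  if (any(genes$start < 0)) stop("negative gene start coordinate")
  bad <- genes$start >= genes$end
  if (any(bad))
    stop(sprintf("degenerate gene interval for '%s' (start >= end)",
                 genes$gene_id[bad][1]))
  invisible(genes)
}

#' Write gene regions as BED4
#' @param genes Gene-region data frame.
#' @param path Output path.
#' @export
write_gene_regions <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "gene_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read CpG position annotation
#'
#' TSV with header columns `cpg_id`, `chrom`, `pos`; positions are 1-based
#' base-pair coordinates.
#'
#' @param path Path to the annotation TSV.
#' @return `data.frame` with columns `cpg_id`, `chrom`, `pos`.
#' @export
read_cpg_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = c(cpg_id = "character",
                                               chrom = "character",
                                               pos = "integer"))
  if (!all(c("cpg_id", "chrom", "pos") %in% colnames(df)))
    stop("annotation needs cpg_id, chrom, pos columns")
  if (anyDuplicated(df$cpg_id)) stop("duplicate cpg_id in annotation")
  if (any(df$pos < 1)) stop("CpG positions are 1-based and must be >= 1")
  df[, c("cpg_id", "chrom", "pos")]
}

#' Write CpG position annotation
#' @param annot Annotation data frame.
#' @param path Output path.
#' @export
write_cpg_annotation <- function(annot, path) {
  utils::write.table(annot[, c("cpg_id", "chrom", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the phenotype and covariate table
#'
#' TSV with header; requires `sample_id`, the pre/post lipid columns
#' (`hdl_pre`, `hdl_post`, `tg_pre`, `tg_post`, mg/dL) and keeps any further
#' covariate columns as supplied.
#'
#' @param path Path to the phenotype TSV.
#' @return `data.frame` with one row per sample.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  df$sample_id <- as.character(df$sample_id)
  validate_phenotypes(df)
  df
}

validate_phenotypes <- function(pheno) {
  need <- c("sample_id", "hdl_pre", "hdl_post", "tg_pre", "tg_post")
  if (!all(need %in% colnames(pheno)))
    stop("phenotype table must contain sample_id and pre/post lipid columns")
  if (anyDuplicated(pheno$sample_id)) stop("duplicate sample_id in phenotypes")
  lip <- as.matrix(pheno[, c("hdl_pre", "hdl_post", "tg_pre", "tg_post")])
  if (anyNA(lip) || any(lip <= 0)) stop("lipid values must be positive")
  invisible(pheno)
}

#' Write the phenotype and covariate table
#' @param pheno Phenotype data frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- pheno
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinship matrix from TSV
#'
#' Header row and first column carry sample ids; body is the symmetric matrix
#' of kinship coefficients.
#'
#' @param path Path to the kinship TSV.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
read_kinship <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, colnames(df)[-1])
  validate_kinship(m)
  m
}

validate_kinship <- function(kin) {
  if (!is.matrix(kin) || nrow(kin) != ncol(kin)) stop("kinship must be square")
  if (max(abs(kin - t(kin))) > 1e-8) stop("kinship matrix is not symmetric")
  if (any(diag(kin) < 0.5 - 1e-8)) stop("kinship diagonal must be >= 0.5")
  if (any(kin < -1e-8) || any(kin > 1 + 1e-8)) stop("kinship entries in [0,1]")
  invisible(kin)
}

#' Write a kinship matrix to TSV
#' @param kin Kinship matrix.
#' @param path Output path.
#' @export
write_kinship <- function(kin, path) {
  df <- data.frame(sample_id = rownames(kin), format_num(kin),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write association results to TSV
#'
#' Columns `unit_id`, `gene_id`, `chrom`, `n_cpgs`, `method`, `statistic`,
#' `df_or_neigs`, `pvalue`; numerics are serialized at 17 significant digits
#' so that write-then-read is lossless.
#'
#' @param results Association-result data frame (possibly zero rows).
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  cols <- c("unit_id", "gene_id", "chrom", "n_cpgs", "method", "statistic",
            "df_or_neigs", "pvalue")
  out <- results[, cols, drop = FALSE]
  out$statistic <- sprintf("%.17g", out$statistic)
  out$pvalue <- sprintf("%.17g", out$pvalue)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association results written by [write_results()]
#' @param path Path to the results TSV.
#' @return Association-result data frame.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    unit_id = "character", gene_id = "character", chrom = "character",
    n_cpgs = "integer", method = "character", statistic = "double",
    df_or_neigs = "integer", pvalue = "double"))
  df
}

## Single constructor for result rows so every test module emits the same shape
association_result <- function(unit_id, method, statistic, df_or_neigs,
                               pvalue, gene_id = "", chrom = "",
                               n_cpgs = 1L) {
  stopifnot(method %in% c("univariate_lm", "univariate_lmm", "pcev", "vc",
                          "vc_family"))
  data.frame(unit_id = unit_id, gene_id = gene_id, chrom = chrom,
             n_cpgs = as.integer(n_cpgs), method = method,
             statistic = as.numeric(statistic),
             df_or_neigs = as.integer(df_or_neigs),
             pvalue = as.numeric(pvalue), stringsAsFactors = FALSE)
}
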