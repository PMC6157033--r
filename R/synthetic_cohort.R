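#' Configuration for the synthetic family cohort generator
#'
#' Bundles and validates every knob of the generator.  Defaults describe the
#' emulated study: 102 three-generation pedigrees (714 members, of whom
#' roughly 300 are mutually unrelated), 20-CpG gene blocks with exchangeable
#' within-block correlation 0.3 on the latent (logit) scale, two latent
#' batch/cell-composition factors loading on both methylation and phenotype,
#' methylation heritability 0.2 and phenotype (lipid-change) heritability
#' 0.3.  `effect_blocks` is a list of `list(gene_id, effect, prop_causal)`
#' entries injecting per-CpG effects (in latent-scale SD units) into the
#' trait named by `effect_trait`.
#'
#' @param n_families Number of families (>= 1).
#' @param family_structure `"trio"` (3 members), `"nuclear2"` (2 parents +
#'   2 children), or `"three_gen"` (7 members over three generations).
#' @param n_genes Number of genes.
#' @param cpgs_per_gene Single count or `c(min, max)` range.
#' @param block_rho Within-block exchangeable correlation on the latent
#'   scale, in `[0, 1)`.
#' @param n_latent Number of latent confounders.
#' @param latent_sd SD of the latent-factor loadings (methylation and
#'   phenotype share the factors).
#' @param meth_h2 Proportion of latent-scale methylation variance from the
#'   additive familial component, in `[0, 1)`.
#' @param effect_blocks List of causal-block specifications (see above).
#' @param pheno_h2 Familial (polygenic) variance proportion of the
#'   lipid-change phenotype, in `[0, 1)`.
#' @param effect_trait Trait receiving the CpG effects, `"tg"` or `"hdl"`.
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 102, family_structure = "three_gen",
                       n_genes = 20, cpgs_per_gene = 20, block_rho = 0.3,
                       n_latent = 2, latent_sd = 1, meth_h2 = 0.2,
                       effect_blocks = list(), pheno_h2 = 0.3,
                       effect_trait = "tg", seed = 1) {
  if (n_families < 1) stop("n_families must be >= 1")
  if (!family_structure %in% c("trio", "nuclear2", "three_gen"))
    stop(sprintf("unknown family structure '%s'", family_structure))
  stopifnot(block_rho >= 0, block_rho < 1,
            meth_h2 >= 0, meth_h2 < 1,
            pheno_h2 >= 0, pheno_h2 < 1,
            latent_sd >= 0, n_latent >= 0)
  if (meth_h2 + block_rho >= 1)
    stop("meth_h2 + block_rho must be < 1 (noise variance would be negative)")
  if (!effect_trait %in% c("tg", "hdl")) stop("effect_trait must be tg or hdl")
  for (eb in effect_blocks) {
    if (!all(c("gene_id", "effect", "prop_causal") %in% names(eb)))
      stop("effect_blocks entries need gene_id, effect, prop_causal")
  }
  structure(list(n_families = n_families,
                 family_structure = family_structure, n_genes = n_genes,
                 cpgs_per_gene = cpgs_per_gene, block_rho = block_rho,
                 n_latent = n_latent, latent_sd = latent_sd,
                 meth_h2 = meth_h2, effect_blocks = effect_blocks,
                 pheno_h2 = pheno_h2, effect_trait = effect_trait,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pedigree of identical family units
#'
#' Family layouts: `trio` = two founder parents and one child; `nuclear2` =
#' two founder parents and two children; `three_gen` = two founder
#' grandparents, their son, his founder spouse and three grandchildren.
#' Fully deterministic (the layout involves no random draws).
#'
#' @param config A [sim_config()].
#' @return Pedigree data frame (`family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex` with 1 = male, 2 = female).
#' @export
simulate_pedigree <- function(config) {
  unit <- switch(config$family_structure,
    trio = data.frame(i = 1:3, f = c(0, 0, 1), m = c(0, 0, 2),
                      sex = c(1, 2, 1)),
    nuclear2 = data.frame(i = 1:4, f = c(0, 0, 1, 1), m = c(0, 0, 2, 2),
                          sex = c(1, 2, 1, 2)),
    three_gen = data.frame(i = 1:7, f = c(0, 0, 1, 0, 3, 3, 3),
                           m = c(0, 0, 2, 0, 4, 4, 4),
                           sex = c(1, 2, 1, 2, 1, 2, 1)))
  rows <- lapply(seq_len(config$n_families), function(fam) {
    fid <- sprintf("F%04d", fam)
    iid <- sprintf("%s_I%d", fid, unit$i)
    data.frame(family_id = fid, individual_id = iid,
               father_id = ifelse(unit$f == 0, "0",
                                  sprintf("%s_I%d", fid, unit$f)),
               mother_id = ifelse(unit$m == 0, "0",
                                  sprintf("%s_I%d", fid, unit$m)),
               sex = as.character(unit$sex), stringsAsFactors = FALSE)
  })
  ped <- do.call(rbind, rows)
  validate_pedigree(ped)
  ped
}

## shared square root of 2*Phi for drawing familial effects
kin_sqrt <- function(kin) {
  eg <- eigen(2 * kin, symmetric = TRUE)
  eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0)))
}

#' Simulate block-correlated, heritable, confounded methylation
#'
#' For each gene a latent Gaussian matrix is built per CpG from: a familial
#' component `a ~ N(0, meth_h2 * 2 Phi)` shared across the block; a
#' block factor `sqrt(block_rho) * u`, `u ~ N(0, I)`, inducing exchangeable
#' within-block correlation; shared latent confounders `F` (`n x n_latent`,
#' standard normal, common to all genes) with per-CpG loadings
#' `N(0, latent_sd^2)`; and independent noise with variance
#' `1 - meth_h2 - block_rho` so the non-confounder part has unit marginal
#' variance.  Beta values are the inverse logit of the latent values plus a
#' per-CpG intercept `Uniform(-2, 2)`.  Genes are laid out 1 Mb apart on
#' chr1 with CpGs placed within 15 kb of the 10 kb gene interval.
#'
#' Draw order (fixed for reproducibility): gene sizes, per-gene positions,
#' latent factors, then per gene: intercepts, loadings, familial vector,
#' block factor, noise.  Seeded with `config$seed + 1`.
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @param kin Kinship matrix consistent with `ped`.
#' @param config A [sim_config()].
#' @return List: `meth` (beta-scale methylation matrix), `annot`, `genes`,
#'   `latent_factors` (`n x n_latent`), `latent_meth` (latent-scale matrix,
#'   used by the phenotype generator for causal effects).
#' @export
simulate_methylation <- function(ped, kin, config) {
  n <- nrow(ped)
  if (nrow(kin) != n) stop("kinship inconsistent with pedigree")
  set.seed(config$seed + 1L)
  sizes <- if (length(config$cpgs_per_gene) == 2)
    sample(config$cpgs_per_gene[1]:config$cpgs_per_gene[2],
           config$n_genes, replace = TRUE)
  else rep(config$cpgs_per_gene, config$n_genes)
  gene_len <- 10000L
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
                      chrom = "chr1",
                      start = (seq_len(config$n_genes) - 1L) * 1000000L,
                      end = (seq_len(config$n_genes) - 1L) * 1000000L +
                        gene_len)
  pos_list <- lapply(seq_len(config$n_genes), function(g) {
    lo <- genes$start[g] - 15000L + 1L
    sort(sample(max(lo, 1L):(genes$end[g] + 15000L), sizes[g]))
  })
  Fmat <- matrix(stats::rnorm(n * config$n_latent), n, config$n_latent)
  A2h <- kin_sqrt(kin)
  noise_sd <- sqrt(1 - config$meth_h2 - config$block_rho)
  blocks <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    p <- sizes[g]
    mu <- stats::runif(p, -2, 2)
    lam <- matrix(stats::rnorm(p * config$n_latent, sd = config$latent_sd),
                  p, config$n_latent)
    a <- sqrt(config$meth_h2) * as.numeric(A2h %*% stats::rnorm(n))
    u <- sqrt(config$block_rho) * stats::rnorm(n)
    E <- matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
    L <- (a + u) + Fmat %*% t(lam) + E   # n x p, shared vectors recycled
    L <- sweep(L, 2, mu, `+`)
    colnames(L) <- sprintf("%s_cg%03d", genes$gene_id[g], seq_len(p))
    blocks[[g]] <- L
  }
  latent <- do.call(cbind, blocks)
  rownames(latent) <- ped$individual_id
  beta <- stats::plogis(latent)
  annot <- data.frame(
    cpg_id = colnames(latent),
    chrom = "chr1",
    pos = unlist(pos_list),
    stringsAsFactors = FALSE)
  list(meth = methylation_matrix(beta, ped$individual_id, colnames(latent),
                                 scale = "beta"),
       annot = annot, genes = genes, latent_factors = Fmat,
       latent_meth = latent)
}

#' Simulate covariates and pre/post lipid phenotypes
#'
#' Covariates: age ~ Uniform(20, 70); sex copied from the pedigree (0/1);
#' smoking ~ Bernoulli(0.25); metabolic syndrome ~ Bernoulli(0.3); center ~
#' categorical over 3 sites; fasting times ~ Uniform(8, 14) hours.  The
#' latent lipid change for each trait is
#' `delta = sum_c beta_c * Ystd_c + gamma' F + g + e` with `Ystd_c` the
#' standardized latent-scale methylation of the causal CpGs (effects only on
#' `effect_trait`), `gamma ~ N(0, latent_sd^2)` on the same latent factors
#' as the methylation, polygenic `g ~ N(0, pheno_h2 * 2 Phi)` and noise
#' variance `1 - pheno_h2`.  Pre-treatment values are log-normal;
#' triglycerides change multiplicatively (`tg_post = tg_pre * exp(delta)`,
#' i.e. delta is the log-ratio) and HDL additively in mg/dL.
#'
#' Seeded with `config$seed + 2`; draw order: covariates, then per trait
#' (hdl first) gamma, polygenic, noise, then pre-treatment values.
#'
#' @param ped Pedigree.
#' @param kin Kinship matrix.
#' @param meth_sim Output of [simulate_methylation()].
#' @param config A [sim_config()].
#' @return Phenotype data frame with a `"truth"` attribute recording the
#'   latent deltas, causal CpG sets and latent factors for recovery tests.
#' @export
simulate_phenotypes <- function(ped, kin, meth_sim, config) {
  n <- nrow(ped)
  set.seed(config$seed + 2L)
  covar <- data.frame(
    sample_id = ped$individual_id,
    age = stats::runif(n, 20, 70),
    sex = as.integer(ped$sex == "2"),
    center = sample(1:3, n, replace = TRUE),
    smoking = stats::rbinom(n, 1, 0.25),
    metabolic_syndrome = stats::rbinom(n, 1, 0.3),
    fast_time_pre = stats::runif(n, 8, 14),
    fast_time_post = stats::runif(n, 8, 14),
    stringsAsFactors = FALSE)
  A2h <- kin_sqrt(kin)
  causal <- list()
  for (eb in config$effect_blocks) {
    gidx <- meth_sim$genes$gene_id == eb$gene_id
    if (!any(gidx))
      stop(sprintf("effect block references unknown gene '%s'", eb$gene_id))
    ids <- meth_sim$annot$cpg_id[startsWith(meth_sim$annot$cpg_id,
                                            paste0(eb$gene_id, "_"))]
    k <- ceiling(eb$prop_causal * length(ids))
    causal[[eb$gene_id]] <- list(cpg_ids = ids[seq_len(k)],
                                 effect = eb$effect)
  }
  delta <- list()
  for (trait in c("hdl", "tg")) {
    gamma <- stats::rnorm(config$n_latent, sd = config$latent_sd)
    gpoly <- sqrt(config$pheno_h2) * as.numeric(A2h %*% stats::rnorm(n))
    eps <- stats::rnorm(n, sd = sqrt(1 - config$pheno_h2))
    dl <- as.numeric(meth_sim$latent_factors %*% gamma) + gpoly + eps
    if (trait == config$effect_trait) {
      for (cb in causal) {
        Yc <- scale(meth_sim$latent_meth[, cb$cpg_ids, drop = FALSE])
        dl <- dl + cb$effect * rowSums(Yc)
      }
    }
    delta[[trait]] <- dl
  }
  tg_pre <- exp(stats::rnorm(n, log(100), 0.4))
  hdl_pre <- exp(stats::rnorm(n, log(50), 0.2))
  pheno <- cbind(data.frame(sample_id = ped$individual_id,
                            hdl_pre = hdl_pre,
                            hdl_post = pmax(hdl_pre + delta$hdl, 0.1),
                            tg_pre = tg_pre,
                            tg_post = tg_pre * exp(delta$tg),
                            stringsAsFactors = FALSE),
                 covar[, -1])
  validate_phenotypes(pheno)
  attr(pheno, "truth") <- list(delta = delta, causal = causal,
                               latent_factors = meth_sim$latent_factors,
                               config = config)
  pheno
}

#' Simulate a complete cohort
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [kinship_from_pedigree()], [simulate_methylation()] and
#' [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return List with `pedigree`, `kinship`, `meth`, `annot`, `genes`,
#'   `phenotypes`, `truth`.
#' @export
simulate_cohort <- function(config) {
  ped <- simulate_pedigree(config)
  kin <- kinship_from_pedigree(ped)
  ms <- simulate_methylation(ped, kin, config)
  pheno <- simulate_phenotypes(ped, kin, ms, config)
  list(pedigree = ped, kinship = kin, meth = ms$meth, annot = ms$annot,
       genes = ms$genes, phenotypes = pheno, truth = attr(pheno, "truth"))
}

#' Write a simulated cohort to a directory
#'
#' Emits every on-disk artifact of the pipeline (methylation TSV, pedigree,
#' gene BED, annotation, phenotypes, kinship) plus a `truth.yaml` manifest
#' of the generating parameters for parameter-recovery tests.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_methylation(cohort$meth, file.path(dir, "methylation.tsv"))
  write_pedigree(cohort$pedigree, file.path(dir, "pedigree.fam"))
  write_gene_regions(cohort$genes, file.path(dir, "genes.bed"))
  write_cpg_annotation(cohort$annot, file.path(dir, "cpg_annotation.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_kinship(cohort$kinship, file.path(dir, "kinship.tsv"))
  truth <- cohort$truth
  manifest <- unclass(truth$config)
  manifest$causal <- lapply(truth$causal, function(cb)
    list(effect = cb$effect, cpg_ids = cb$cpg_ids))
  yaml::write_yaml(manifest, file.path(dir, "truth.yaml"))
  invisible(dir)
}
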