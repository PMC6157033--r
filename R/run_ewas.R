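#' Assemble and validate an analysis configuration
#'
#' Accepts either a named list or a path to a YAML file with the same
#' fields.  Input datasets may be given as file paths (`meth`, `annot`,
#' `genes`, `pheno`, `pedigree`, all in the package's on-disk formats) or
#' as the in-memory objects the readers produce.
#'
#' @param config Named list or YAML path.  Recognized fields and defaults:
#'   `trait` (`"tg"`), `change_definition` (`NULL` = trait default),
#'   `covariates` (age, sex, center, smoking, metabolic_syndrome and both
#'   fasting times), `n_probes` (2000, capped at the array size), `k_pcs`
#'   (4; 0 disables PC adjustment), `seed` (1), `flank` (20000),
#'   `max_block_size` (130), `methods` (univariate, pcev, vc, plus
#'   vc_family / univariate_family when a pedigree is given), `fwer_alpha`
#'   (0.10), `unrelated_threshold` (0.0221), `scale` (`"beta"`),
#'   `fast_lmm_approx` (`FALSE`), `out_dir`.
#' @return Validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    trait = "tg", change_definition = NULL,
    covariates = c("age", "sex", "center", "smoking", "metabolic_syndrome",
                   "fast_time_pre", "fast_time_post"),
    n_probes = 2000, k_pcs = 4, seed = 1, flank = 20000,
    max_block_size = 130, methods = c("univariate", "pcev", "vc"),
    fwer_alpha = 0.10, unrelated_threshold = 0.0221, scale = "beta",
    fast_lmm_approx = FALSE, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  stopifnot(config$trait %in% c("hdl", "tg"),
            config$scale %in% c("beta", "logit"),
            config$fwer_alpha > 0, config$fwer_alpha < 1)
  known <- c("univariate", "pcev", "vc", "vc_family", "univariate_family")
  if (!all(config$methods %in% known))
    stop("unknown method in config$methods")
  for (nm in c("meth", "annot", "genes", "pheno", "pedigree")) {
    if (is.character(config[[nm]]) && !file.exists(config[[nm]]))
      stop(sprintf("input file for '%s' does not exist: %s", nm,
                   config[[nm]]))
  }
  class(config) <- "analysis_config"
  config
}

load_input <- function(x, reader, scale = NULL) {
  if (is.character(x)) {
    if (is.null(scale)) reader(x) else reader(x, scale = scale)
  } else x
}

stage <- function(name, unit, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed at unit '%s': %s", name, unit,
                 conditionMessage(e)), call. = FALSE))
}

## covariate design: expand categorical columns, keep numerics as is
covariate_design <- function(pheno, covariates) {
  if (!length(covariates)) return(NULL)
  miss <- setdiff(covariates, colnames(pheno))
  if (length(miss))
    stop(sprintf("covariate '%s' missing from phenotype table", miss[1]))
  df <- pheno[, covariates, drop = FALSE]
  for (nm in colnames(df)) {
    if (is.character(df[[nm]]) || nm == "center")
      df[[nm]] <- factor(df[[nm]])
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]   # intercept re-added by the tests themselves
}

#' Run the full region-based EWAS pipeline
#'
#' Orchestrates trait preparation, confounder-PC construction, CpG-to-gene
#' assignment and block splitting, optional greedy selection of unrelated
#' individuals, the requested association tests, Bonferroni thresholds at
#' the configured FWER, genomic-inflation factors and Q-Q tables, plus
#' top-5 summary tables per method.  Unrelated-sample methods
#' (`univariate`, `pcev`, `vc`) run on the greedily selected unrelated
#' subset whenever a pedigree is supplied; family methods (`vc_family`,
#' `univariate_lmm` via `univariate_family`) use all samples with the
#' pedigree kinship.  Identical config and seed yield byte-identical output
#' files.
#'
#' @param config An [analysis_config()] (list or YAML path accepted).
#' @return Invisible list with `results` (per method), `lambda`,
#'   `thresholds`, `qq`, `top`, `counts`, `unrelated_ids`; files are written
#'   under `config$out_dir` when set.
#' @export
run_ewas <- function(config) {
  config <- analysis_config(config)
  meth <- stage("read_methylation", "-",
                load_input(config$meth, read_methylation,
                           scale = config$scale))
  annot <- stage("read_annotation", "-",
                 load_input(config$annot, read_cpg_annotation))
  genes <- stage("read_genes", "-", load_input(config$genes,
                                               read_gene_regions))
  pheno <- stage("read_phenotypes", "-", load_input(config$pheno,
                                                    read_phenotypes))
  ped <- if (is.null(config$pedigree)) NULL else
    stage("read_pedigree", "-", load_input(config$pedigree, read_pedigree))
  if (!is.character(config$meth) && config$scale == "logit" &&
      attr(meth, "meth_scale") == "beta")
    meth <- methylation_matrix(beta_logit(meth), rownames(meth),
                               colnames(meth), scale = "logit")
  ids <- pheno$sample_id
  if (!all(ids %in% rownames(meth)))
    stop("phenotype samples missing from methylation matrix")
  meth <- meth[ids, , drop = FALSE]
  x_all <- prepare_trait(pheno, config$trait, config$change_definition)
  kin <- NULL
  if (!is.null(ped)) {
    kin <- stage("kinship", "-", kinship_from_pedigree(ped))[ids, ids]
  }
  unrel <- ids
  if (!is.null(kin))
    unrel <- stage("select_unrelated", "-",
                   select_unrelated(kin, config$unrelated_threshold))
  blocks <- stage("build_blocks", "-",
                  build_blocks(annot, genes, flank = config$flank,
                               max_block_size = config$max_block_size))
  annotated_cpgs <- sort(unique(blocks$cpg_id))
  counts <- list(n_cpgs_in = ncol(meth),
                 n_cpgs_annotated = length(annotated_cpgs),
                 n_blocks = length(unique(blocks$block_id)),
                 n_samples = length(ids), n_unrelated = length(unrel))
  message(sprintf(
    "cpgset: %d CpGs in, %d annotated, %d blocks, %d samples, %d unrelated",
    counts$n_cpgs_in, counts$n_cpgs_annotated, counts$n_blocks,
    counts$n_samples, counts$n_unrelated))

  ## confounder design per sample subset
  build_C <- function(sub) {
    Ccov <- covariate_design(pheno[match(sub, ids), , drop = FALSE],
                             config$covariates)
    if (config$k_pcs > 0) {
      n_probes <- min(config$n_probes, ncol(meth))
      probes <- stage("sample_probes", "-",
                      sample_probes(meth[sub, , drop = FALSE], n_probes,
                                    seed = config$seed, annot = annot))
      pcs <- stage("compute_pcs", "-",
                   compute_pcs(meth[sub, , drop = FALSE], probes,
                               k = config$k_pcs))
      Ccov <- cbind(Ccov, pcs$scores)
    }
    Ccov
  }

  block_ids <- unique(blocks$block_id)
  block_info <- blocks[!duplicated(blocks$block_id), ]
  block_cpgs <- split(blocks$cpg_id, blocks$block_id)[block_ids]

  results <- list()
  for (method in config$methods) {
    fam <- method %in% c("vc_family", "univariate_family")
    sub <- if (fam) ids else unrel
    x <- x_all[sub]
    C <- build_C(sub)
    M <- meth[sub, , drop = FALSE]
    res <- switch(method,
      univariate = {
        r <- stage("univariate", "-",
                   cpg_lm_test_many(x, C, M[, annotated_cpgs, drop = FALSE]))
        r$gene_id <- ""
        r$chrom <- annot$chrom[match(r$unit_id, annot$cpg_id)]
        r
      },
      univariate_family = {
        keig <- eigen(2 * kin, symmetric = TRUE)
        nullm <- if (config$fast_lmm_approx)
          fit_null_lmm(x, C, kin, kin_eigen = keig, compute_P0 = FALSE)
        else NULL
        do.call(rbind, lapply(annotated_cpgs, function(cg)
          stage("univariate_family", cg, {
            r <- cpg_lmm_test(x, C, M[, cg], kin, cpg_id = cg,
                              fast = config$fast_lmm_approx, null = nullm,
                              kin_eigen = keig)
            r$chrom <- annot$chrom[match(cg, annot$cpg_id)]
            r
          })))
      },
      pcev = {
        do.call(rbind, lapply(block_ids, function(b)
          stage("pcev", b, {
            fit <- fit_pcev(M[, block_cpgs[[b]], drop = FALSE], x, C)
            info <- block_info[block_info$block_id == b, ]
            association_result(b, "pcev", fit$h2, fit$p,
                               pcev_test_analytic(fit),
                               gene_id = info$gene_id, chrom = info$chrom,
                               n_cpgs = length(block_cpgs[[b]]))
          })))
      },
      vc = {
        nullm <- stage("fit_null_lm", "-", fit_null_lm(x, C))
        do.call(rbind, lapply(block_ids, function(b)
          stage("vc", b, {
            qf <- vc_score_test(nullm, x, M[, block_cpgs[[b]],
                                            drop = FALSE])
            info <- block_info[block_info$block_id == b, ]
            association_result(b, "vc", qf$Q, qf$n_eigs, qf$pvalue,
                               gene_id = info$gene_id, chrom = info$chrom,
                               n_cpgs = length(block_cpgs[[b]]))
          })))
      },
      vc_family = {
        if (is.null(kin)) stop("vc_family requires a pedigree")
        nullm <- stage("fit_null_lmm", "-", fit_null_lmm(x, C, kin))
        do.call(rbind, lapply(block_ids, function(b)
          stage("vc_family", b, {
            qf <- vc_score_test(nullm, x, M[, block_cpgs[[b]],
                                            drop = FALSE])
            info <- block_info[block_info$block_id == b, ]
            association_result(b, "vc_family", qf$Q, qf$n_eigs, qf$pvalue,
                               gene_id = info$gene_id, chrom = info$chrom,
                               n_cpgs = length(block_cpgs[[b]]))
          })))
      })
    rownames(res) <- NULL
    results[[method]] <- res
  }

  lambda <- vapply(results, function(r)
    if (nrow(r) >= 10) genomic_inflation(r$pvalue) else NA_real_,
    numeric(1))
  thresholds <- vapply(results, function(r)
    bonferroni_threshold(config$fwer_alpha, nrow(r)), numeric(1))
  qq <- lapply(results, function(r) qq_data(r$pvalue))
  top <- lapply(results, function(r) {
    r <- r[order(r$pvalue, r$unit_id), ]
    utils::head(r, 5)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (method in names(results)) {
      write_results(results[[method]],
                    file.path(config$out_dir,
                              sprintf("results_%s_%s.tsv", method,
                                      config$trait)))
      utils::write.table(
        data.frame(expected = sprintf("%.17g", qq[[method]]$expected),
                   observed = sprintf("%.17g", qq[[method]]$observed)),
        file.path(config$out_dir, sprintf("qq_%s_%s.tsv", method,
                                          config$trait)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_results(top[[method]],
                    file.path(config$out_dir,
                              sprintf("top5_%s_%s.tsv", method,
                                      config$trait)))
    }
    manifest <- list(seed = config$seed, trait = config$trait,
                     scale = config$scale, fwer_alpha = config$fwer_alpha,
                     counts = counts,
                     lambda = as.list(lambda),
                     bonferroni_threshold = as.list(thresholds))
    yaml::write_yaml(manifest, file.path(config$out_dir,
                                         "run_manifest.yaml"))
  }
  invisible(list(results = results, lambda = lambda,
                 thresholds = thresholds, qq = qq, top = top,
                 counts = counts, unrelated_ids = unrel))
}
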