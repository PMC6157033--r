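#' Derive the analyzed lipid-change trait
#'
#' Triglyceride changes are analyzed on the log scale
#' (`log(tg_post) - log(tg_pre)`, a log-ratio) because TG is right-skewed;
#' HDL changes as plain differences in mg/dL.  Either definition can be
#' forced for either lipid.
#'
#' @param pheno Phenotype table (see [read_phenotypes()]).
#' @param trait `"hdl"` or `"tg"`.
#' @param change_definition `"difference"` or `"log_ratio"`; defaults to
#'   `"log_ratio"` for TG and `"difference"` for HDL.
#' @return Named numeric vector (names = sample ids).
#' @export
prepare_trait <- function(pheno, trait = c("hdl", "tg"),
                          change_definition = NULL) {
  trait <- match.arg(trait)
  if (is.null(change_definition))
    change_definition <- if (trait == "tg") "log_ratio" else "difference"
  if (!change_definition %in% c("difference", "log_ratio"))
    stop("change_definition must be 'difference' or 'log_ratio'")
  pre <- pheno[[paste0(trait, "_pre")]]
  post <- pheno[[paste0(trait, "_post")]]
  if (change_definition == "log_ratio") {
    bad <- pre <= 0 | post <= 0
    if (any(bad))
      stop(sprintf("nonpositive lipid value for sample '%s' under log_ratio",
                   pheno$sample_id[bad][1]))
    out <- log(post) - log(pre)
  } else {
    out <- post - pre
  }
  names(out) <- pheno$sample_id
  out
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / m
}

#' Genomic inflation factor lambda
#'
#' Transforms p-values to 1-df chi-square quantiles and divides their median
#' by the null median 0.4549364; lambda near 1 indicates calibrated tests,
#' above 1 inflation (confounding or unmodeled relatedness).
#'
#' @param pvalues Vector of p-values in (0, 1], length >= 10.
#' @return Lambda.
#' @export
genomic_inflation <- function(pvalues) {
  if (length(pvalues) < 10) stop("need at least 10 p-values")
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  chi <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chi) / 0.4549364
}

#' Quantile-quantile table for p-values
#'
#' @inheritParams genomic_inflation
#' @return `data.frame` with `expected` and `observed` columns, both on the
#'   `-log10` scale, expected at `(i - 0.5) / m` and observed sorted
#'   ascending.
#' @export
qq_data <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  m <- length(pvalues)
  ## rank-matched: i-th smallest p against the (i - 0.5)/m uniform quantile
  data.frame(expected = -log10((rev(seq_len(m)) - 0.5) / m),
             observed = -log10(sort(pvalues, decreasing = TRUE)))
}
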