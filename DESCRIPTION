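Package: cpgset
Title: Region-Based CpG-Set Association Tests for Methylation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Region-based epigenome-wide association testing of quantitative
    traits against blocks of correlated CpG methylation sites.  Implements the
    principal component of explained variation (PCEV) dimension-reduction test
    with an exact analytic null and a permutation fallback, a variance-component
    (SKAT-type) score test with mixture-of-chi-square p-values by
    characteristic-function inversion, and family-aware variants of both the
    region and per-CpG tests through a pedigree-kinship linear mixed model.
    Includes pedigree kinship computation, greedy selection of a maximal
    unrelated subset, assignment of CpG sites to gene regions with flanking
    windows, block splitting, methylation-derived confounder principal
    components, Bonferroni family-wise error control, genomic-inflation
    diagnostics, and a generator of synthetic family-structured methylation
    cohorts for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
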