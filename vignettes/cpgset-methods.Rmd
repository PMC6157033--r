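---
title: "Region-based CpG-set association testing: models, defaults, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based CpG-set association testing: models, defaults, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgset)
```

## The problem

Epigenome-wide association studies test hundreds of thousands of CpG
methylation sites against a phenotype, and the Bonferroni correction for
that many tests costs a great deal of power.  When the phenotype of
interest is a treatment response — here, the change in HDL or (log)
triglycerides after lipid-lowering therapy — single-CpG signals are often
too weak to survive correction.  `cpgset` instead tests *sets* of
neighbouring CpGs (a gene plus flanking sequence, split into blocks of at
most 130 sites) so that correlated signal is pooled and the number of
tests drops by an order of magnitude, while adjusting for known covariates
and for unknown technical/cell-composition structure through
methylation-derived principal components, and accommodating family data
through pedigree-kinship mixed models.

Throughout, `Y` is the `n x p` methylation block, `x` the length-`n` trait
(lipid change), and `C` the `n x r` confounder matrix (an intercept is
always included by the fitting functions).

## The two region tests

### Principal component of explained variation (PCEV)

PCEV seeks the loading vector `w` maximizing
\[
h^2(w) \;=\; \frac{\operatorname{Var}\!\big[\widehat{E}(Yw \mid x)\big]}
                  {\operatorname{Var}(Yw)},
\]
the fraction of variance of the component `Yw` explained by the trait,
after both `Y` and `x` are residualized on `C`.  Writing `V_G` for the
cross-product of fitted values of the column-wise regression of
residualized `Y` on residualized `x` and `V_R` for the residual
cross-product, `w` is the leading eigenvector of `V_R^{-1} V_G` and
`h^2 = d/(1+d)` with `d` the leading eigenvalue.  Testing
`corr(Yw, x) = 0` naively would use the data twice; the correct null is
`h^2(w) = 0`.  Because the hypothesis has rank one (a single trait), the
largest root has an exact F transformation under Gaussian residuals,

\[ F = d\,\frac{n - r - p}{p} \sim F(p,\; n - r - p), \]

the one-predictor case of Roy's largest-root test, where it coincides
with Hotelling's \(T^2\).  `pcev_test_analytic()` implements this form;
`pcev_test_permutation()` permutes the residualized trait and recomputes
`h^2`, giving an assumption-light check with p-value floor
`1/(n_perm+1)`.  The two agree within Monte Carlo error across null and
signal datasets (this is asserted in the test suite), which is the
package's internal validation of the analytic null.  The eigenproblem is
solved through the Cholesky factor of `V_R` (symmetric congruent form),
with a `1e-10` relative diagonal jitter retried once if `V_R` is
numerically singular, e.g. for exactly duplicated probes.

PCEV requires `p <= n - r - 2`; oversized gene sets must be split into
blocks first, which is exactly what the 130-site cap provides.

### Variance-component (SKAT-type) score test

The reverse model treats `x` as the response and lets the block act on its
*variance*: `x = C beta + f(Y) + e` with `f ~ N(0, tau K)`,
`K = Z Z'`, and `Z` the column-centered block.  The score statistic for
`tau = 0` is

\[ Q = x' P_0 K P_0 x, \qquad
   P_0 = V^{-1} - V^{-1} C (C' V^{-1} C)^{-1} C' V^{-1}, \]

with `V = sigma_e^2 I` for unrelated samples (so `P_0` is the residual
projection scaled by the REML variance) or
`V = sigma_g^2 \cdot 2\Phi + sigma_e^2 I` for families, where `Phi` is the
pedigree kinship matrix.  Under the null `Q` is distributed as
`sum_j lambda_j chi^2_1` with `lambda_j` the eigenvalues of
`P_0^{1/2} K P_0^{1/2}`, computed as the (cheaper) eigenvalues of
`Z' P_0 Z`.  Probe weights default to 1 — methylation predictors are
common-scale, unlike rare variants, so no frequency-based weighting is
applied — and columns are centered but not scaled by default
(`scale_option = "standardize"` switches this on).

### Mixture-of-chi-square tails

`davies_pvalue()` inverts the characteristic function through Imhof's
integral.  The integrand oscillates as `sin(theta(u))/(u rho(u))` with
unimodal `theta`, so the integral is evaluated piecewise between the zeros
of the sine factor (located by root-finding; each piece is smooth and
single-signed) and the infinite alternating tail is summed by Euler
transformation.  This reproduces chi-square tails to near machine
precision and agrees with an independent convolution oracle at `1e-8`.
When the inversion fails or returns a value outside `(0, 1]` — which
happens only in extreme tails where the alternating series loses relative
accuracy — the Liu moment-matching approximation (first three cumulants
matched to a scaled noncentral chi-square) is substituted and flagged in
`method_used`.  Eigenvalues are truncated at `1e-10` of the largest to
suppress numerical noise in near-singular kernels.

## Family structure

`kinship_from_pedigree()` applies the classical recursion in topological
order (founders unrelated, `phi_ii = 1/2 + phi_fm/2`,
`phi_ij = (phi_{fj} + phi_{mj})/2`), handling inbred loops naturally.
`fit_null_lmm()` estimates `(sigma_g^2, sigma_e^2)` by REML, profiling the
ratio `delta = sigma_g^2/sigma_e^2` on a 41-point log grid spanning
`[1e-5, 1e5]` refined by golden-section search, in the eigenbasis of
`2 Phi` (decomposed once and reusable across fits via `kin_eigen`).  REML
rather than ML is used because variance components feed directly into the
score-test null; a `boundary` flag marks fits pinned at the grid edge
(typically a zero familial component).  The per-CpG family test
(`cpg_lmm_test()`) is a Wald test with variance components re-estimated
under the alternative for every CpG (exact mode) or reused from the
covariate-only null (`fast = TRUE`), a deliberate exact-versus-fast
trade-off.  The Wald statistic is referred to a `t` distribution with
`n - p` degrees of freedom rather than a normal, so that with an identity
relationship matrix the test collapses *exactly* onto the OLS t-test; for
family cohorts of the sizes simulated here the two references differ
negligibly.

For methods that require independent subjects, `select_unrelated()`
builds the relatedness graph at a kinship threshold (default 0.0221,
about \(2^{-5.5}\) — below half-first-cousins, so any pair sharing a
pedigree ancestor is split) and greedily deletes the highest-degree
vertex, breaking ties by the lexicographically smallest sample id for
cross-platform determinism.  Greedy deletion alone does not guarantee
maximality, so a final pass re-admits (in original row order) anyone no
longer adjacent to a survivor; the returned set is then a maximal
independent set, verified exhaustively in the tests on small pedigrees.

## Regions, confounder PCs, multiplicity

CpGs are assigned to a gene when their 1-based position `p` satisfies
`s - flank < p <= e + flank` against the gene's 0-based half-open
`[s, e)` — the single place where the two coordinate conventions meet.
The flank defaults to 20 kb on both sides; strand is ignored since the
window is symmetric.  A CpG inside several overlapping windows is tested
in each; unannotated CpGs are dropped.  Gene sets larger than
`max_block_size` (130) are cut into `ceiling(p/130)` contiguous,
as-equal-as-possible chunks — contiguity preserves the local correlation
that makes region testing worthwhile, and the equal split is a declared
convention (the alternative, position-based cutting, is not implemented).

Unknown confounding (cell purity, batch) is adjusted by the top `k = 4`
principal components of 2000 randomly sampled autosomal probes
(`sample_probes()` honours chromosome labels when an annotation is
supplied).  Scores are left singular vectors scaled by singular values of
the column-centered probe submatrix, with the largest-magnitude loading
of each component made positive for determinism.  PCs are computed on the
beta scale by default, mirroring the analysis scale choice below.

Family-wise error is controlled by Bonferroni at `alpha/m`, with
`alpha = 0.10` by default and `m` the number of tests the run actually
performed for each method.  Diagnostics are the genomic inflation factor
(median 1-df chi-square quantile over 0.4549364) and rank-matched Q-Q
tables.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates the statistical structure the analysis
assumes: identical family units (trio, two-child nuclear, or
seven-member three-generation), kinship-heritable methylation
(`a ~ N(0, meth_h2 * 2 Phi)` shared across a block), exchangeable
within-block correlation `block_rho` through a per-sample block factor,
latent confounders loading on both methylation and the phenotype (the
mechanism that biases unadjusted p-values and is removed by the PCs),
per-CpG intercepts `Uniform(-2, 2)` pushed through the inverse logit so
beta values stay in `(0, 1)`, and pre/post lipid values with the
triglyceride change defined on the log scale (multiplicative response)
and the HDL change additive.  Causal effects act on the latent (logit)
scale of standardized causal CpGs, keeping beta values in range.

Default conditions: 102 three-generation families (714 members, of whom
306 are mutually unrelated at the default threshold — the preset family
shapes are stand-ins, chosen to match the emulated cohort's total size
rather than its exact pedigree composition), 20 genes of 20 CpGs,
`block_rho = 0.3`, `meth_h2 = 0.2`, `pheno_h2 = 0.3`, two latent factors
with loading SD 1.  Covariates (age, sex, study center, smoking,
metabolic syndrome, two fasting times) are drawn from simple parametric
families and carry no effect on the trait — they exercise the adjustment
machinery, not the biology.

The generator does *not* emulate: realistic 450K probe spacing or
beta-value bimodality beyond what random intercepts induce, SNP
genotypes, cell-type mixtures with reference profiles, or
heteroscedastic boundary variance.  Passing calibration and power checks
on these cohorts therefore validates the statistical machinery under its
own assumptions; it does not certify behaviour on real arrays, where
(for example) methylation heritability not captured by pedigree kinship
is known to inflate family-based tests.  That mismatch case is
documented, not resolved: when the generative model matches the fitted
model the family tests are calibrated, which is the level this package
can test.

## Numerical and design choices

* **Analysis scale.**  Beta values are analyzed as-is by default, with a
  logit (`M-value`) option (`scale = "logit"`, clipping at `1e-6` to keep
  boundary values finite) since near-boundary heteroscedasticity can
  distort normality-based nulls.  The choice is a config switch; no
  default equivalence between the scales is asserted.
* **Missing data** are a hard error: no imputation rule is defensible
  without a stated mechanism, and silent dropping changes `n` per CpG.
* **Determinism.**  Every stochastic step takes an explicit seed; the
  generator documents its draw order, and identical config plus seed
  yields byte-identical output files (numerics serialized at 17
  significant digits round-trip losslessly).
* **Degenerate inputs.**  Constant CpGs yield p = 1 with a warning in
  per-CpG tests and are dropped from kernels; an all-constant block short
  circuits to p = 1; rank-deficient covariates and oversized PCEV blocks
  raise instructive errors rather than proceeding.
* **Problem sizes in the checks.**  The packaged validation suite runs
  calibration at 1500-6000 null replicates (6000 for the per-CpG family
  LMM, whose Monte Carlo error is largest relative to the acceptance
  band; its size at the simulated conditions measures 0.052), inflation
  diagnostics on 2000 CpGs at n = 300, heritability recovery over 200
  fits at n = 600, and the power comparison over 150-200 cohorts of 400
  subjects.
* **Power comparison operating point.**  With half of a 20-CpG block
  carrying 0.3-SD per-CpG effects at n = 400, both the region test and
  the univariate minimum-p scan reject essentially always (region
  p-values are many orders of magnitude smaller, but binary power
  saturates at 1 for both), so the packaged comparison plants 0.03-SD
  per-CpG effects — chosen by a pilot power scan to put both methods in
  the interior-power regime — and holds each method to `alpha/m` with its
  own test count.  There the pooled test's advantage is visible as a
  power gap (roughly 0.70 versus 0.47 at 150 replicates) rather than a
  saturated tie.

## Known limitations

PCEV is limited to a single trait (`x` is one column) and `p < n - r`;
the VC test has no SKAT-O style omnibus, no rare-variant weights, and no
small-sample moment correction; the univariate family test's Wald
reference is first-order.  The family tests correct only the relatedness
encoded in the pedigree: heritable methylation beyond pedigree kinship —
reported in real treatment-response cohorts — will leave residual
inflation that these corrections cannot remove.  Normalization (e.g.
batch harmonization) is assumed done upstream; the package consumes
already-normalized beta values.
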