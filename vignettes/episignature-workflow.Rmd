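---
title: "Deriving and evaluating blood DNA methylation episignatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating blood DNA methylation episignatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsig)
library(dplyr)
```

## The problem

Pathogenic variants in genes that regulate chromatin — and copy-number
variants spanning such genes — often leave a reproducible mark on the blood
methylome: a set of CpG sites whose methylation jointly distinguishes
carriers from non-carriers. Such an *episignature* is clinically useful
because it can classify a variant of unknown significance (VUS) as
functionally pathogenic or benign from a standard blood methylation array,
complementing sequence-based prediction. methsig implements the full
workflow on Illumina 450K/EPIC-style beta values: probe quality control,
batch mean-centering, variance filtering, reference-based blood cell-type
deconvolution, per-CpG differential testing, intersection-based signature
derivation, region-level confirmation by bootstrap bump hunting,
median-reference correlation classification, and genomic-feature enrichment.

Because real patient cohorts of this kind are small and rarely released, the
package ships a first-class synthetic-data module that emulates the
statistical structure the analysis assumes, so every stage is tested end to
end against known ground truth.

## The model

A methylation **beta value** $\beta \in [0,1]$ is the methylated fraction at
a CpG probe. For a two-group comparison (cases vs controls) the per-probe
model fitted by `fit_moderated_model()` is ordinary least squares on the
beta scale,

$$\beta_{ij} = \alpha_i + \delta_i\,\mathrm{case}_j + \gamma_i\,\mathrm{age}_j
  + \eta_i\,\mathrm{sex}_j + \sum_k \lambda_{ik} w_{kj} + \varepsilon_{ij},$$

where $w_{kj}$ are estimated blood cell-type proportions (one cell type
dropped to keep the design full rank) and $\delta_i$ is the
covariate-adjusted group effect. Per-probe residual variances $s_i^2$ (on
$d$ degrees of freedom) are shrunk towards a common prior by empirical
Bayes: a scaled inverse chi-square prior $(d_0, s_0^2)$ is estimated by
method of moments on $\log s_i^2$ (Newton inversion of the trigamma
function), the posterior variance is
$\tilde s_i^2 = (d_0 s_0^2 + d s_i^2)/(d_0 + d)$, and the moderated
$t = \hat\delta_i / (\tilde s_i \sqrt{v})$ is referred to a t-distribution
on $d_0 + d$ degrees of freedom. Two boundary cases are handled exactly:
when the observed variances show no excess dispersion the prior degrees of
freedom are infinite and $s_0^2$ is the arithmetic mean of the $s_i^2$ (the
unbiased estimate on the raw scale), with the total degrees of freedom
capped at the pooled residual df; forcing $d_0 = 0$ recovers the ordinary
per-probe t-test.

Independently, `mann_whitney_per_probe()` runs a rank-based Mann-Whitney U
test per probe — midranks for ties, an exact two-sided p-value from the
enumerated null distribution when there are no ties and $n_1 n_2 \le 400$,
otherwise a normal approximation with tie and continuity corrections. Both
p-vectors are Benjamini-Hochberg adjusted separately over the
variance-filtered probe set.

The **signature** (`derive_signature()`) is the conservative intersection:

$$\text{CpG } i \in S \iff q^{\text{limma-style}}_i < q^\ast
  \;\wedge\; q^{\text{MWU}}_i < q^\ast \;\wedge\; |\Delta\beta_i| \ge 0.05,$$

with $\Delta\beta_i$ the raw difference of group means. The defaults are
$q^\ast = 0.05$ for the primary signature and $q^\ast = 0.01$ for the
stringent signature used for classification; by construction the stringent
signature is nested in the primary one. An `unadjusted_p` mode (raw
regression $p < 0.001$, $|\Delta\beta| \ge 0.05$) supports the screening
situation where nothing survives FDR correction.

### Classification

`build_reference_profiles()` computes the per-CpG **median** over training
cases and over training controls at the signature sites. A sample's score is

$$\mathrm{score} = r(\beta_{\text{sample}}, \text{case medians})
 - r(\beta_{\text{sample}}, \text{control medians}),$$

with $r$ the Pearson correlation over the available signature probes
(Spearman available behind an option; Pearson is the default because the
beta-scale profiles are the quantity of interest and no rank distortion is
expected at a few hundred sites). Positive scores are case-like; the
decision threshold is fixed at 0 with ties called control-like, matching
the use of borderline negative scores for mosaic carriers. Cross-platform
scoring (`intersect_platform()`) restricts the signature to probes present
on the scoring platform and refuses to proceed below 10 probes — scores are
never imputed.

### Regional confirmation

`find_candidate_regions()` clusters position-sorted probes into maximal
same-sign runs with per-probe $|\Delta\beta| \ge 0.05$ and inter-probe gaps
$\le 500$ bp. The region statistic is the area $\sum |\Delta\beta|$.
Significance comes from a residual bootstrap
(`bootstrap_region_pvalues()`): a covariates-only null model is fitted per
probe, residual columns are resampled with replacement, discovery is re-run
on each null matrix, and the per-iteration **maximum** null area is
recorded, giving family-wise control across candidates;
$p = (1 + \#\{\max A^\ast \ge A\})/(B+1)$ with add-one smoothing so $p$ is
never exactly 0. Reported DMRs additionally need $p < 0.05$,
$|\overline{\Delta\beta}| \ge 0.05$, at least 3 CpGs, and overlap with the
episignature. Whether the original region method permuted labels or
resampled residuals is not documented beyond a package citation; the
residual bootstrap was chosen because it preserves the covariate structure
under the null, and this choice is recorded rather than asserted. No loess
smoothing is applied to the $\Delta\beta$ track: at array probe density the
raw thresholding rule is the stated candidate definition.

### Deconvolution and enrichment

`estimate_cell_proportions()` solves, per sample,
$\min_w \|\beta_{\text{markers}} - M^\top w\|^2$ subject to $w \ge 0$,
$\sum w = 1$, by projected gradient descent with exact Euclidean projection
onto the probability simplex (step $1/L$ with $L$ the spectral bound,
iterate-change tolerance $10^{-8}$, cap 20,000 iterations). The simplex
constraint (rather than $\sum w \le 1$) is used because the proportions
enter the regression as covariates, where dropping one cell type then
avoids collinearity.

`feature_enrichment()` tests each annotation category with two one-sided
hypergeometric tails against the variance-filtered background of the same
comparison — never the full array — reporting enrichment and depletion
separately at $p < 0.05$ (both tails include $P(X = k)$, so they sum to at
least 1). No correction across categories is applied, matching the
per-category reporting convention; the per-category p-values are printed so
users can apply one. `gene_overlap_test()` applies the same tail to gene-set
overlaps within a stated universe; gene lists are plain-text user inputs.

## What the synthetic data emulate

`generate_cohort()` draws per-probe baseline means from a bimodal
logit-normal (two components at logit $\pm 2.2$, SD 1.0), reproducing the
characteristic two-peaked beta distribution and its heteroscedasticity near
0 and 1 — which the variance filter must see. Gaussian noise (default SD
0.03, a typical replicate-level array SD) is added on the beta scale and
values clipped to $[10^{-6}, 1-10^{-6}]$. Planted case effects are additive
on the beta scale so the recorded truth $\Delta\beta$ carries the same
semantics as the analysis effect size; baselines at planted probes are
redrawn so both group-generating means stay inside $(0,1)$, making truth
deltas exact rather than truncated. Optional structure: per-year age slopes
and sex offsets at random probe subsets, per-batch mean shifts, and
cell-type mixtures $W M$ at marker probes with per-sample Dirichlet
proportions (defaults emulate whole-blood composition, concentration 30).
Cell structure is deliberately confined to marker probes so the confound
stays localised and testable. The fitted generative model is stored in the
cohort object; `draw_samples()` draws independent carriers or controls from
the same model, and a `baseline` argument lets several cohorts share one
population methylome — required for cross-model exclusivity checks.

What the generator does **not** emulate: Infinium I/II probe chemistry and
its type bias, spatial chip artefacts, genetic (meQTL) effects, correlated
probe blocks beyond planted regions, and non-Gaussian outlier samples.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative assumptions, not robustness to every
artefact of real arrays.

## Reference study conditions and problem sizes

The packaged evaluation mirrors two training comparisons: a deletion-like
cohort of 9 cases vs 23 controls with 115 planted CpGs and
$|\Delta\beta| \in [0.08, 0.23]$, and a chromatin-modifier-like cohort of
7 vs 21 with 422 planted CpGs and $|\Delta\beta| \in [0.05, 0.54]$, both at
noise SD 0.03 on a 20,000-probe manifest. Held-out evaluation uses 7
carrier test samples and 162 independent controls. The 20,000-probe
manifest keeps a full derivation around ten seconds while leaving the
multiple-testing burden realistic in structure; recovery and null-control
suites use 2,000–10,000 probes and 10–20 seeds. On these conditions the
derived signatures recover essentially all planted probes, held-out
carriers all score positive, independent controls score negative under both
the primary and stringent models, purified cell-type profiles score
negative under both signatures, and carriers of one planted effect score
negative under the other model (the planted sets are disjoint).

## Numerical choices and edge cases

* Regression is on beta values, not M-values: the thresholds and
  $\Delta\beta$ semantics are beta-scale, and consistency between the test
  and the reported effect outweighs the variance-stabilisation argument.
  This is an open modelling choice, exposed as such.
* Sample SDs use the $n-1$ denominator throughout.
* `bh_adjust()` delegates to the standard step-up implementation after
  validating inputs; an independent brute-force implementation of the
  definition lives in the test suite.
* Mean-centering with a single batch is the identity; a batch with a single
  sample is an error because correcting it would zero the probe
  deterministically.
* An all-constant matrix under a positive variance-filter fraction retains
  nothing, with a warning.
* Exact Mann-Whitney p-values are claimed only for tie-free data; midranks
  plus the corrected normal approximation handle ties.
* A score of exactly 0 is called control-like; degenerate (constant)
  reference or sample vectors are errors, not silent NAs.
* One config seed feeds stage-salted generators, so changing the bootstrap
  iteration count does not perturb cohort generation.
* Coordinates: manifests are 1-based; BED exports are 0-based half-open.

## Known limitations

Only two-group case/control contrasts are supported (no interactions or
surrogate variables); normalisation from raw intensities (IDAT), probe-type
bias correction, and kernel-smoothed DMR callers are out of scope; the
enrichment module bundles no gene-set databases. The classifier is
deliberately simple — a fixed sign rule on a correlation difference — and
produces no calibrated probability; this matches its intended use as a
transparent VUS triage aid rather than a machine-learning classifier.

## A minimal run

```{r example, eval = FALSE}
man <- generate_manifest(20000, seed = 1)
usable <- man$probe_id[!(man$sex_chrom_flag | man$cross_reactive_flag |
                           man$snp_5bp_flag | man$nonspecific_flag)]
targets <- withr::with_seed(2, sample(usable, 115))
cohort <- generate_cohort(man, 9, 23,
                          effects = effect_spec(targets, c(0.08, 0.23)),
                          seed = 11)

vf <- variance_filter(filter_probes(cohort$beta, man)$beta, 0.02)
fit <- fit_moderated_model(vf$beta, cohort$samples)
mwu <- mann_whitney_per_probe(vf$beta, cohort$samples)
deltas <- compute_delta_beta(vf$beta, cohort$samples)
sig <- derive_signature(fit, mwu, deltas, q_thresh = 0.05)

refs <- build_reference_profiles(
  cohort$beta, sig,
  cohort$samples$sample_id[cohort$samples$group == "case"],
  cohort$samples$sample_id[cohort$samples$group == "control"])
carriers <- draw_samples(cohort, 7, "case", seed = 12)
score_samples(carriers$beta[sig$probe_id, ], refs)
```

The same flow, driven by files and a config object, is available through
`pipeline_config()` + `run_pipeline()`, which writes the signature tables,
DMR BED/TSV, scores, enrichment table and a JSON run report recording every
threshold applied.
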