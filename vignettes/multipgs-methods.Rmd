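---
title: "Multi-polygenic scores by penalized combination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-polygenic scores by penalized combination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(multipgs)
```

## The problem

A polygenic score (PGS) summarizes a person's genetic liability to a trait as
a weighted sum of allele dosages, with weights derived from GWAS summary
statistics. Because pleiotropy is pervasive — variants that alter coronary
heart disease (CHD) risk also move lipid levels, blood pressure, type 2
diabetes risk, and other atherosclerotic disease — a score built only from a
CHD GWAS leaves information on the table. multipgs implements the full
workflow for building a *multi-PGS*: combine many single-trait scores into
one score for a target disease by a lasso logistic regression in a tuning
cohort, then collapse the fitted combination back into a single
variant-level scoring file that can be applied to any new cohort with
ordinary scoring software.

The package covers five stages, each usable on its own:

1. **Summary statistics** — case-control effective sample sizes, variant QC,
   fixed-effects inverse-variance meta-analysis with genomic control.
2. **Scoring** — reading PGS Catalog style scoring files, harmonizing
   variants against cohort genotypes, computing per-sample scores.
3. **Combination** — lasso logistic regression of the outcome on many PGS
   with unpenalized covariates, penalty chosen by cross-validation.
4. **Collapse** — turning the fitted combination into one scoring file.
5. **Evaluation** — odds ratios per SD, Nagelkerke $R^2$, AUC, bootstrap
   intervals, decile prevalence, likelihood-ratio tests, and FDR-controlled
   association scans over large PGS libraries.

A sixth module simulates pleiotropic multi-trait cohorts so that every stage
runs, and is testable, without access to any real biobank.

## Models and formulas

### Effective sample sizes

For a case-control GWAS with $N$ samples and case proportion $p$, the total
effective sample size is $4p(1-p)N$ — the size of the balanced study with
the same power. Per variant, with allele frequency $f$ and reported standard
error $SE$, the effective sample size is $4 / (2f(1-f)\,SE^2)$, clamped to
$[0.5, 1.1] \times$ the study total. The raw formula inverts the
approximate variance of a marginal log-odds estimate; the clamp guards
against unreliable standard errors near frequency extremes. `multipgs`
applies the clamp per input study (`per_snp_effective_n()`), before any
meta-analysis.

### Meta-analysis and genomic control

`ivw_meta()` is a fixed-effects inverse-variance combination: weights
$w_i = 1/SE_i^2$, combined $\beta = \sum w_i \beta_i / \sum w_i$,
$SE = (\sum w_i)^{-1/2}$. Alleles are aligned to the first table carrying
each variant; a swapped effect/other pair flips the sign, anything else
drops the variant with a logged count — strand flips are deliberately not
guessed at this stage (strand-ambiguous sites are removed later, at
scoring). Variants present in a single study are carried through with a
`n_studies = 1` flag rather than dropped: the package favors downstream
coverage, and the flag lets a stricter analyst filter them. Genomic control
divides association $\chi^2$ statistics by
$\lambda_{GC} = \mathrm{median}(z^2)/0.4549364$ (the $\chi^2_1$ median,
stated to seven digits for reproducibility); it is applied per study, before
combination, and only when $\lambda_{GC} > 1$ — deflation is never applied.

### Variant QC

`qc_filter()` applies the standard biobank thresholds — MAF $\ge$ 1%,
imputation info $\ge$ 0.3, call rate $\ge$ 0.99, HWE $p \ge 10^{-6}$ — with
each filter active only when its column exists, and reports a per-filter
exclusion tally. The HWE test is the 1-df chi-square goodness of fit at the
sample allele frequency; monomorphic sites are defined to pass. The
chi-square approximation tracks an exact multinomial enumeration to within
an order of magnitude for moderate deviations, which is the regime the
$10^{-6}$ filter operates in; an exact test is a possible extension.

### Scoring and harmonization

`harmonize()` matches scoring rows to cohort variants on (chromosome,
position) — 1-based, VCF convention — with allele verification: exact match
keeps the weight, swapped effect/other alleles negate it, A/T and C/G pairs
are removed as strand-ambiguous, duplicated scoring rows keep their first
occurrence, cohort sites with more than two alleles are removed, and
variants absent from the cohort get weight zero (the collapse stage relies
on that convention). The score is $s_i = \sum_j d_{ij} w_j$; missing
dosages are mean-imputed as $2 \times$ MAF. rsID matching is not used: the
synthetic data carries no rsIDs, and positional matching with allele
verification is sufficient for harmonized inputs.

### The lasso combination

With outcome $y$, standardized PGS matrix $X$ and covariates $C$ (age, sex,
principal components), `fit_lasso_logistic()` minimizes

$$ -\tfrac{1}{n}\,\ell(y;\, \beta_0 + C\gamma + X\beta) \;+\;
   \lambda \lVert \beta \rVert_1 $$

over the PGS coefficients only — intercept and covariates are never
penalized. The solver is iteratively reweighted least squares with cyclic
coordinate descent and soft-thresholding on the penalized block, with the
unpenalized block solved exactly inside each weighted least-squares
subproblem (covariance updating keeps each coordinate update $O(K)$).
Numerical choices, stated because they matter for reproducibility:

* penalty path: 100 values, geometric from $\lambda_{\max}$ (the largest
  absolute deviance gradient at the covariate-only fit — not the null
  intercept fit, because covariates are unpenalized) down to
  $10^{-4}\lambda_{\max}$;
* convergence: maximum coefficient change below $10^{-7}$; IRLS weights
  floored at $10^{-5}$; step-halving keeps the penalized deviance
  non-increasing across outer iterations;
* separation: capped iterations with a warning rather than divergence;
* cross-validation: 10 folds, stratified by case status (stratification
  stabilizes the deviance curve at 10% prevalence), seeded shuffle; a fold
  that would leave one outcome class triggers a logged refold with an
  offset seed;
* `lambda.min`: the penalty minimizing mean CV binomial deviance; exact
  ties break toward the larger penalty (sparser model).

PGS columns are standardized internally to mean 0, sample SD 1, and
coefficients are reported on that standardized scale. The choice is not
cosmetic: the collapse formula divides each coefficient by the PGS's
standard deviation in the tuning cohort, and reporting on the standardized
scale makes $\beta_k/\sigma_k$ apply to raw scoring-file weights exactly,
whichever scale the scores entered on. Solutions are verified in the test
suite against an unpenalized IRLS fit at $\lambda = 0$, against a generic
convex optimizer's objective value at $\lambda > 0$, and against the
Karush–Kuhn–Tucker conditions along the path.

One behavior worth knowing: `lambda.min` optimizes predictive deviance, not
support recovery, and it is deliberately liberal — with many pure-noise
candidate scores it typically admits a few of them with small coefficients.
That costs little predictive accuracy (which is what the multi-PGS is for)
but means the active set should not be read as a list of "validated"
traits.

### Collapse

Given components $k$ with coefficients $\beta_k$ (standardized scale) and
tuning-cohort standard deviations $\sigma_k$, the combined weight of
variant $j$ is

$$ w_j \;=\; \sum_k \frac{\beta_k}{\sigma_k}\, w_{jk}, $$

with $w_{jk} = 0$ when variant $j$ is absent from component $k$, allele
orientation reconciled before summation, and zero-coefficient components
dropped. `verify_collapse()` checks the algebraic identity this implies —
scoring a cohort with the combined file must equal
$\sum_k (\beta_k/\sigma_k)\,\mathrm{PGS}_k$ to floating-point accuracy
($<10^{-8}$) — and `run_pipeline()` refuses to continue if it does not.
Up to the per-sample constant absorbed by standardization, the collapsed
score is exactly the lasso's PGS contribution, so evaluation of the
combined file is evaluation of the fitted model.

### Evaluation

* **OR per SD**: the score is standardized by its sample SD (the same
  convention as $\sigma_k$ above, which is why the package uses $n-1$
  throughout), a logistic model with covariates is fit, and
  $e^{\hat\beta}$ is reported with a Wald 95% interval.
* **Nagelkerke $R^2$**: Cox–Snell $1 - e^{2(\ell_0-\ell_1)/n}$ rescaled by
  its maximum $1 - e^{2\ell_0/n}$. Its bootstrap interval uses seeded
  percentile resampling of whole rows, 1000 replicates by default; a
  resample on which the statistic fails is redrawn (at most 10 times,
  logged).
* **AUC**: the Mann–Whitney estimator computed from midranks, with ties
  counted half. The 95% interval is DeLong by default (a bootstrap interval
  is available by flag); which interval the field's published tables use is
  often unstated, and DeLong is the cheaper, deterministic choice.
* **Decile prevalence**: samples are ranked (ties broken by stable input
  order — quantile-edge assignment differs between implementations, so the
  rule is pinned), cut into 10 bins whose sizes differ by at most one, and
  the case fraction reported per bin; the size-weighted mean equals the
  overall prevalence exactly.
* **PGS scan**: one logistic fit per candidate score with covariates,
  Benjamini–Hochberg at 5% FDR across the tested scores. Constant columns
  are skipped with a log entry and excluded from the BH denominator (this
  changes the thresholds, so it is stated); a score hitting separation uses
  a ridge-stabilized fallback ($10^{-6}$) and is flagged instead of
  halting a several-thousand-column scan.

## The synthetic-data generator

The generator exists because the real inputs of a multi-PGS study —
biobank-scale genotypes and released GWAS summary statistics — cannot ship
with a package. It emulates the statistical structure the analysis relies
on, with a liability-threshold model standing in for real diagnoses:

* **Genotypes**: two independent allele draws per sample at each variant's
  MAF (Hardy–Weinberg), MAFs uniform on a configurable range (default
  0.05–0.5). No linkage disequilibrium by default: the combination and
  evaluation mathematics do not require LD to be exercised, and LD-aware
  weight construction is explicitly out of the package's scope.
* **Effects**: a `causal_fraction` of variants, shared across traits,
  receives effect sizes from a zero-mean multivariate normal whose
  cross-trait correlation matrix is the pleiotropy dial; remaining variants
  are exact zeros.
* **Phenotypes**: trait liability is the standardized genetic value scaled
  to variance $h^2$ plus independent normal noise of variance $1-h^2$; a
  sample is a case when liability exceeds the normal quantile at
  $1 - \text{prevalence}$. Covariates (age, sex, PCs) are independent noise
  by default so that score effects are identifiable in tests.
* **Summary statistics**: one marginal logistic regression per variant
  (vectorized Newton–Raphson; agrees with `glm` to $10^{-6}$), with
  monomorphic variants flagged rather than dropped, and QC columns (info,
  call rate, HWE p) filled in.
* **Weight files**: a threshold-and-shrink rule (`p <= threshold`, weights
  $= \beta \times$ shrink). This is plumbing, not an LD-aware Bayesian
  shrinkage method; with threshold 1 and shrink 1 it reduces to marginal
  log-odds weights.

Every generator is a pure function of its seed; one master seed propagates
to all stages through a documented multiplicative hash (`split_seed()`),
so module results are reproducible in isolation and whole pipelines are
byte-identical on rerun.

**What passing tests on these data do and do not show.** They show the
pipeline's algebra and statistics behave as specified under the assumed
generative model: calibrated nulls, correct optimizers, an exact collapse,
and — the central scientific property — that held-out AUC of the multi-PGS
exceeds the single-trait PGS precisely when the auxiliary traits are
genetically correlated with the target, and not otherwise. They do not show
performance on real data, where LD, imputation error, ascertainment,
covariate–outcome correlation, and phenotyping noise all exist; no number
produced from these simulations estimates any real cohort's AUC or $R^2$.

## Study sizes used by the checks

The package's heavier checks fix one set of desk-scale study conditions,
chosen once as a realistic liability-threshold power setting: 10 traits
(the target plus three auxiliary traits at genetic correlation 0.6 and six
uncorrelated), 500 variants with causal fraction 0.1, $h^2 = 0.3$,
prevalence 0.1, GWAS cohorts of 3000, tuning and evaluation cohorts of
4000. Under these conditions the multi-PGS gains roughly 0.03 AUC over the
single-trait score when pleiotropy is present, and nothing when it is
absent — a desk-scale reproduction of the motivating phenomenon, run over
20 seeded replicates in each arm. The demo pipeline and acceptance script
use six traits, 2000 variants, and cohorts of 4000.

## Known limitations

* No LD, no imputation-quality simulation, no ancestry structure: gains
  measured here isolate pleiotropy and will differ from real cohorts.
* The shrinkage rule for weight construction is intentionally naive;
  externally built scoring files (PRS-CS, clumping+thresholding, ...) can
  be dropped in via `read_scoring_file()`.
* Strand-ambiguous variants are removed, never inferred from frequency.
* `lambda.min` does not perform support recovery (see above).
* Precision/recall at a classification threshold is not reported: it
  depends on an operating point the package has no basis to choose.
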