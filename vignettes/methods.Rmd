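---
title: "Methods: from 5hmC-Seal counts to a gastric cancer progression risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from 5hmC-Seal counts to a gastric cancer progression risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific problem

Gastric premalignant lesions — chronic inflammation, atrophy with
intestinal metaplasia (IM), and low-grade dysplasia — progress to gastric
adenocarcinoma (GAC) at very different rates, and current endoscopic
surveillance identifies only a minority of the patients who will progress.
5-hydroxymethylcytosine (5hmC) is a stable oxidation product of 5mC,
enriched over the gene bodies of actively expressed genes; the 5hmC-Seal
assay chemically labels 5hmC-containing DNA fragments and sequences them,
so genome-wide fragment counts over genomic features act as a quantitative
readout of the epigenetic state of a biopsy.

`hmcprog` implements a complete, tested analysis path from such counts to
a progression risk model:

1. fragment-to-feature summarization (gene bodies, promoters,
   H3K4me1/H3K27ac enhancer peaks) and metagene profiling;
2. median-of-ratios library-size normalization and parametric
   empirical-Bayes batch adjustment;
3. per-feature differential hydroxymethylation (fold changes, rank-sum
   p-values with the field's empirical halving convention, BH FDR,
   volcano calls, a covariate-adjusted logistic screen, sample
   clustering);
4. bootstrapped elastic-net stability selection of a gene panel;
5. a multivariable logistic risk model on the panel plus clinical
   covariates, evaluated by ROC/AUC with bootstrap confidence intervals
   and a specificity-anchored decision cutoff;
6. a cohort epidemiology layer (descriptive tables, person-years,
   Kaplan-Meier cumulative incidence, Cox proportional hazards, nomogram
   point scaling, standardized incidence ratios, chi-square and power
   utilities).

Patient-level data of the motivating study are not publicly deposited, so
the package ships synthetic-data generators with known ground truth; every
stage is tested by parameter recovery against that truth, by independent
brute-force oracles, or by exact arithmetic on a fixture that reproduces
the published cohort tables.

## Synthetic data: what the generators emulate

### Count generator

`simulate_counts()` draws negative-binomial counts with

```
mu[g, s]  = sf[s] * b[g] * 2^(delta[g] * case[s]) * 2^(shift[batch[s]])
var[g, s] = mu + phi * mu^2
```

Defaults are the study conditions of the motivating cohort: 21 progression
cases versus 48 matched controls; planted |log2 fold changes| drawn
uniformly from [0.26, 1] (0.26 is a 20% fold change, the smallest effect
the differential stage calls) on a random 5% of features with random sign;
per-sample library scale factors log-uniform on [0.5, 2]; dispersion
`phi = 0.2`, a typical overdispersion for 5hmC-Seal gene-body counts;
baseline means log-uniform between 20 and 2000. Batches, when enabled, are
assigned round-robin within each case/control group (so batch is
orthogonal to status, as in a sensibly randomized experiment) and act
multiplicatively on counts while being recorded as log2 shifts in the
truth object, which is what makes batch-adjustment recovery testable. At
desk scale the default feature count is 2,000 rather than the ~20k gene
bodies of a genome-wide run; tests state their sizes explicitly.

What the generator does *not* emulate: GC and mappability bias, read-level
error, fragment-length variation, correlated features (co-regulated gene
modules), and case/control imbalance in age or gender (ages and genders
are drawn identically for both groups, matching the matched design).
Passing tests therefore demonstrate correctness of the statistical
machinery under a clean generative model, not robustness to artefacts of
real libraries.

### Fragment generator

`simulate_fragments()` places fragment midpoints on the toy genome implied
by a feature catalog with per-base density proportional to a weight per
feature class and uniform placement within a class. It exists to test the
midpoint counting rule and the metagene profile (gene-body enrichment,
TSS depletion) against constructions whose answer is known exactly.

### Cohort generator

`simulate_cohort()` draws exponential event times under a proportional
hazards model `h = h0 * exp(sum of log HRs)` with administrative censoring.
Defaults mirror the published 29,176-patient gastritis cohort: lesion mix
17,948 / 10,391 / 837 (inflammation / atrophy-IM / dysplasia), 40.84% male,
the published age-group mix, univariate hazard ratios (dysplasia 7.049,
atrophy/IM 1.994 versus inflammation; female 0.395; age groups 1.886 /
4.136 / 6.088 versus <50), and maximum follow-up 21.59 years. The baseline
hazard 2.6e-4 per person-year was calibrated once so that the expected
overall GAC incidence over follow-up is close to the cohort's printed
0.82%: with the mix-averaged hazard multiplier of ~2.5 and mean follow-up
of ~12.7 years, `29176 * (2.6e-4 * 2.5) * 12.7 ~ 240` events. Exponential
(constant-hazard) times rather than Weibull keep the generator inside the
assumptions of the Cox test surface; age is drawn uniformly within
age-group bounds (70+ capped at 94, the oldest age at diagnosis in the
published tables) because only group membership matters downstream.

### The published-table fixture

`make_fixture("table12_cohort")` builds, deterministically, a
29,176-patient cohort whose *marginals* equal the published baseline and
outcome tables: lesion x gender, lesion x age group, lesion x location,
GAC events split into first-year (time <= 1) and later, event gender and
age at diagnosis, the printed medians of time to diagnosis (pinned by
order statistics of a monotone time ramp), total person-years
(370,561.99, calibrated exactly by a power-curve censoring ramp) and a
median follow-up of 12.2 years (anchored by a plateau of censoring times).
The joint distribution beyond those marginals is arbitrary. Two printed
cells are internally inconsistent in the source tables (the 70+ age counts
do not partition two lesion groups, and one male-dysplasia percentage
disagrees with its own denominator); the fixture uses the harmonized
counts that make all rows and columns partition exactly, and the
inconsistent cells are excluded from assertions.

## Normalization and batch adjustment

`size_factors()` implements the median-of-ratios estimator: for sample
*s*, the median over features (restricted to features with positive counts
in every sample) of `count[g, s] / geometric_mean(count[g, ])`, rescaled
to geometric mean 1. When no all-positive feature exists the function
demands an explicit pseudocount rather than silently switching
conventions. Accuracy under the default generator (2,000 features,
dispersion 0.2) is ~1.2% mean absolute relative error per sample, with a
worst sample around 3%; this is the intrinsic noise of a median over
2,000 overdispersed ratios, and the DESeq2 reference estimator returns the
same factors to 1e-8.

`normalize_log()` produces `log2(count / sf + pseudocount)` with a default
pseudocount of 1.

`combat_adjust()` is a parametric empirical-Bayes location/scale batch
adjustment: per-feature standardization under a design that contains the
batch indicators plus *protected* biological covariates (case/control
group, age, gender — protecting the group prevents the adjustment from
absorbing true signal), per-batch location and scale estimates shrunk to
moment-matched normal and inverse-gamma priors by the usual iterated
posterior equations, then subtraction, rescaling and restoration of the
covariate fit. Two deliberate numerical choices:

- per-batch scale estimates use the maximum-likelihood (n) denominator,
  consistent with the pooled variance; this makes the adjustment exactly
  idempotent on pure-shift batch effects, at the cost of order-1/n
  differences from implementations that mix denominators;
- when a prior is degenerate (zero feature-to-feature variance of the
  location or scale estimates — e.g. an identical shift on every feature)
  the posterior collapses onto the prior mean, which removes a constant
  shift *exactly*; singleton batches and batch-covariate aliasing are
  errors, not warnings.

## Differential analysis

Fold changes are computed from size-factor-scaled count means with a
pseudocount, `log2((mean_case + 1) / (mean_control + 1))`, not from model
coefficients; this reproduces the 0.26 <-> 20% correspondence exactly and
decouples the fold change from dispersion estimation.

`wilcoxon_empirical_p()` reports the two-sided rank-sum p-value (exact
when `n1 * n2 <= 400` and the pooled sample is tie-free, otherwise the
normal approximation with tie and continuity correction) together with the
"empirical" p-value defined as the two-sided p divided by two — the
convention used in the 5hmC literature this package mirrors. The
convention is implemented verbatim and documented rather than endorsed:
under no ties it equals the one-sided p-value in the observed direction,
so on a pure null the fraction of features with empirical p below 0.05 is
about 0.10 (the raw-p fraction below 0.1), i.e. the halving doubles the
null pass rate at any fixed threshold. The property suite asserts exactly
this consequence.

BH q-values (`bh_fdr()`, step-up, computed on the empirical p-values, the
scale on which all calls are made) back the clustering-grade calls
(FDR < 0.05, fold change > 20%); volcano calls use strict inequalities
`|log2FC| > 0.26` and `empirical p < 0.05`, so a feature at exactly 0.26
is not called. Recovery tests use a planted-dominated matrix (100 planted
features at |log2FC| = 1 among 200) because a <= 10% false-call fraction is
arithmetically impossible under the volcano rule at genome-scale null
fractions; at those sizes recovery is complete with ~6% false calls.

`covariate_screen()` fits, per feature, `status ~ value + age_z + gender`
by logistic regression and keeps features with Wald p < 0.01 for the value
coefficient — the candidate list from which stability selection starts.
Perfectly separating features are retained with p = 0 and a flag rather
than refit under a penalty: the screen only ranks candidates, and a
feature that separates 21 cases from 48 controls is exactly what the
next stage should see. Age is z-scored for conditioning.

`hierarchical_cluster()` uses 1 - Pearson correlation between samples and
average linkage, with columns pre-sorted lexicographically so that ties
break deterministically.

## Stability selection

The selection procedure follows the bootstrapped elastic-net recipe: 100
class-stratified bootstrap resamples of the training set; on each
resample, five-fold stratified cross-validation over a grid of the mixing
parameter alpha in [0.05, 1] and penalty strength lambda in [1e-5, 1],
choosing the pair that minimizes mean held-out binomial deviance (ties
resolve to the larger lambda, then the larger alpha); a full-precision
refit at the chosen pair; features scoring above 20 on the importance
scale are marked; the panel is the set of features marked in at least 80%
of resamples.

Numerical and design choices:

- **Importance** is the max-scaled standardized coefficient magnitude
  `100 * |beta_j| * sd(X_j) / max_k |beta_k| * sd(X_k)` — the conventional
  0-100 variable-importance scale; an all-zero model scores everything 0.
- **Grids.** The default grid is 5 alpha values (0.05-1) by 30 log-spaced
  lambda values. Measured on planted-signal data, selection frequencies
  under a 20 x 50 grid agree with the coarse grid to within one bootstrap
  step while costing four times as much; grid resolution buys nothing
  because retention is frequency-based, not estimate-based.
- **Fold fits** use a relaxed coordinate-descent threshold (1e-5): the
  held-out deviance ranking is insensitive to the final digits of fold
  coefficients, and only the refit at the chosen pair (threshold 1e-7)
  contributes coefficients to the importance scores.
- **Seeds.** Each bootstrap iteration derives its own seed from the master
  seed by a stable counter hash, so any single iteration can be reproduced
  in isolation.
- A one-standard-error variant (`cv_rule = "1se"`) is available; it is not
  the default because, measured on planted-signal data at these sample
  sizes, it degrades recovery (it prefers large-lambda near-ridge models
  whose importance ranking is driven by marginal correlations).

**Known, measured limitations of the procedure at p >> n.** Two
behaviours of the selection recipe at these problem sizes (n = 46
training samples, p = 2000 features) are documented by deliberately
failing acceptance checks rather than hidden:

- *Pure noise does not yield empty panels.* Among thousands of features,
  the strongest spurious correlate of the labels is a property of the
  dataset, not of a particular fold or resample; it improves held-out
  deviance coherently across cross-validation folds, enters the chosen
  model in most bootstrap resamples, and carries maximal importance
  whenever the model is non-empty. No deviance-based selection rule can
  prefer the empty model in this regime (argmin and the 1-SE rule were
  both measured; 0/10 empty panels each), and stability selection's
  false-positive control — which assumes selection probabilities spread
  over many exchangeable features — does not apply when a single
  correlate dominates.
- *Moderate planted effects clear the retention floor only unreliably.*
  A feature shifted by 1.2 sd has a two-sample t of ~3.7 at 14 vs 32,
  barely above the maximum-noise t over 2000 features (~3.4), so its
  membership in the chosen support fluctuates across bootstrap resamples:
  measured per-feature selection frequencies range from ~0.1 to 1.0
  across data replicates, and demanding that *three* such features
  simultaneously reach the 0.8 frequency floor (with at most two false
  features) succeeds only in a minority of replicates. Frequencies are
  monotone in the effect size and rise toward 1 as the planted effect
  approaches 2 sd.

In practice the package's defenses are the covariate screen upstream
(which passes ~1% of null features, so the selector sees tens rather than
thousands of candidates) and the held-out validation split downstream (a
noise panel does not generalize: permuted-label validation AUC centres at
0.5).

## The risk model

The final model is unpenalized logistic regression (IRLS, tolerance 1e-8,
at most 50 iterations) of progression status on the panel features plus
gender, age (z-scored) and lesion type (indicator columns, inflammation
reference), fitted on the training split only. Detected separation
(diverging coefficients or non-convergence) triggers a ridge refit and a
flag; with 14 cases and 32 controls and a multi-gene panel, separation is
common and the flag is part of the result, not an error. The fallback
penalty defaults to 1 on the information scale (`separation_ridge`
argument): a nominal penalty like 1e-6 is numerically no regularizer —
it leaves coefficients of order 1e3 along a separating hyperplane chosen
by noise, which we measured to cost up to 0.4 of validation AUC on data
whose true discriminant direction scores 0.94 — whereas a unit ridge pins
the direction to the data while remaining negligible for non-separated
fits (which never see it). Risk scores are the linear predictor, monotone
in the fitted probability but free of the exact ties that probability
saturation creates under separation; per-sample probabilities are also
reported.
The published model statement that cohort hazard ratios were "added into"
the final model is implemented as an optional offset: a Cox linear
predictor can enter the linear predictor with coefficient fixed at 1
(`offset =` argument, default off) — the most literal reading that keeps
the model identifiable.

Evaluation: empirical ROC curves with simultaneous steps at tied scores
(so the trapezoidal AUC equals the Mann-Whitney probability with 1/2 tie
credit — asserted against the rank-sum identity exhaustively on small
score sets); stratified bootstrap percentile confidence intervals (2,000
resamples by default; percentile rather than BCa is adequate at n = 69 and
trivially reproducible); the decision cutoff is the threshold maximizing
sensitivity among those achieving at least 90% specificity on the
validation set (ties to the larger threshold), then sensitivity and
specificity are reported on all samples pooled. When saturated scores tie
so that no observed threshold reaches the floor, cutoff selection errors
with a diagnostic; the end-to-end wrapper degrades to a missing cutoff
with a warning so permutation-null studies can still evaluate AUCs.

## Epidemiology layer

- `cohort_summary()` reproduces the published table layout: percentages
  are of the lesion-group column total, rounded half-up (not banker's
  rounding) to two decimals; the first year means `time <= 1.0`.
- `cox_ph_fit()` wraps the Newton-Raphson partial-likelihood fit with
  Breslow tie handling (the convention of the original analysis software);
  monotone-likelihood designs abort with a convergence error. Confidence
  intervals are Wald, `exp(beta +/- 1.96 se)`.
- `nomogram_points()` rescales each covariate's effect so the largest
  effect range spans 100 points and every reference level scores 0;
  survival probabilities at a horizon come from the Breslow baseline
  cumulative hazard.
- `sir()` is observed events over `sum(rate * person_years)` across
  age-gender-calendar strata; an expected count of zero with positive
  observed events is an error.
- `power_two_sample()` is the noncentral-t power of the two-sided
  two-sample t-test (`ncp = d * sqrt(n1 n2 / (n1 + n2))`). It is provided
  as a general utility; at 21 versus 48 samples, 80% power at alpha = 0.05
  corresponds to d of about 0.74, slightly below the 0.783 sometimes
  quoted for this design, so the function reports what the computation
  gives rather than forcing a quoted value.

## Problem sizes used by the test and acceptance suites

All sizes are the package's own choices for a single-CPU desk-scale run
and are fixed in the test code: differential and screening checks use
2,000-feature matrices at the study's 21/48 sample sizes; stability
selection checks use 6 planted and 6 pure-noise replicates at n = 46
training samples x 2,000 features with 3 planted features at 1.2 sd and
100 bootstraps each; the risk-model check uses 25 replicates with a
nine-gene panel at 0.8 sd per gene plus 15 permuted-label replicates;
Cox recovery uses one 50,000-patient cohort; the Kaplan-Meier, BH, AUC,
Wilcoxon and chi-square oracles are exhaustive or near-exhaustive at small
n. The acceptance script (`scripts/acceptance.R`) recomputes the
headline quantities from scratch at the same sizes under a caller-supplied
seed.

## Known limitations

- The generators draw independent features; correlated gene modules,
  which inflate stability-selection false positives further, are not
  modelled.
- The empirical-p halving convention is reported as defined in the source
  literature; it is not a calibrated one-sided test under ties.
- The nomogram's survival mapping uses the Breslow baseline at the
  covariate reference, not a mean-covariate reference.
- Reproducing the exact published nine-gene panel identity is out of
  scope: it would require the original, non-deposited patient data. The
  procedure, not the panel, is the artifact.
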