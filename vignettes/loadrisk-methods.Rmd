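---
title: "Methods: polygenic + phenotypic KNN risk prediction for LOAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic + phenotypic KNN risk prediction for LOAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`loadrisk` implements a complete case/control risk-prediction pipeline for
late-onset Alzheimer's disease (LOAD): a control-standardized polygenic
score, APOE diplotype encoding, clinical covariates, a k-nearest-neighbours
classifier with configurable distance, rebalancing and decision threshold,
and the inferential battery used to characterize the cohort. This vignette
is the package's own account of the modelling choices, the tunable
parameters, and what the bundled synthetic cohort generator does and does
not emulate.

## The prediction problem

The target is a binary case/control label (LOAD diagnosis) in an elderly
cohort (recruitment ages 60–99). Predictors are of two kinds:

* **Genetic.** Effect-allele dosages at a panel of risk SNPs (379 by
  default) with GWAS effect sizes taken as given, plus the two APOE coding
  SNPs rs429358 and rs7412.
* **Clinical.** Age (years), sex (0 = female, 1 = male), smoking status,
  diabetes (0/1), and total cholesterol (mmol/L).

Cohorts of this kind are strongly imbalanced (the default emulates a 23:77
case:control ratio), which drives two design features: training-set
rebalancing and sensitivity-first threshold tuning.

## The polygenic score and why the "+1" offset is harmless

The raw score is `sum((g_i + 1) * |beta_i|)` with `g_i` the risk-oriented
dosage: when `beta_i < 0` the dosage is flipped (`2 - d`) so that the
"risk homozygote" is always the genotype that increases the score. The
`+ 1` makes every per-SNP term strictly positive (1/2/3 coding). Because
the final feature is the control-standardized z-score
`(raw - mu_control) / sigma_control`, any constant offset `c` in `g + c`
adds the same `(c - 1) * sum(|beta|)` to every individual and cancels
exactly; the test suite asserts this to 1e-12. The orientation itself is
equally inert: signed `beta * dosage` differs from the oriented form only
by a constant, so z-scores agree either way.

`mu_control` and `sigma_control` (and the per-SNP imputation means, and the
column scaler) are computed on **training controls only** and applied
unchanged to test data. The alternative — standardizing on all controls —
is statistically leaky; we chose the leakage-safe contract throughout and
expose no switch that silently mixes test information into training.

Missing genotypes that survive QC (at most 10% per SNP) are imputed with
the mean risk-oriented dosage of the (training) control group at that SNP;
`"overall_mean"` and `"zero"` are available alternatives in
`polygenic_scores()`.

## APOE diplotypes from unphased genotypes

ε2 = (rs429358-T, rs7412-T), ε3 = (T, C), ε4 = (C, C). From unphased
C-allele counts the diplotype is resolved assuming the vanishingly rare ε1
haplotype is absent: every C at rs429358 is assigned to an ε4 haplotype,
and remaining T alleles at rs7412 to ε2. This makes the call total over all
nine genotype combinations and resolves the classic double-heterozygote
ambiguity (ε2/ε4 vs ε1/ε3) to ε2/ε4, the standard convention. The ordinal
risk code (−1, 0, 1, 2 for lower/standard/elevated/high risk) is scaled
together with all other columns before KNN; we preferred uniform scaling
over leaving the code raw because the classifier is distance-based and a
differently-scaled column would silently reweight it.

## Quality control

Four exclusion rules, strict thresholds, one pass:

1. zero observed variance (an all-missing SNP counts as zero-variance);
2. SNP missing rate **>** 0.10 (exactly 10% survives);
3. MAF **<** 0.01 (exactly 0.01 survives), computed over observed
   genotypes only;
4. individuals with **>** 10% missing genotypes, assessed on the retained
   SNP set.

SNPs are filtered before individuals and SNP statistics are *not*
recomputed after individual removal; `apply_qc(iterate = TRUE)` repeats
both filters to a fixed point for users who want the stricter variant.
When several rules match one SNP the recorded reason follows the
precedence zero-variance → missingness → MAF; this affects reporting only.

## The classifier

`knn_probability()` returns the case fraction among the k nearest training
rows. Numerical choices that matter:

* **Distances.** Euclidean, Manhattan, cosine (`1 - cos` angular
  dissimilarity; a zero-norm vector is an error, not a silent 0).
* **Ties.** Equal distances are broken by training-row order via a stable
  sort. On continuous features ties have probability zero and predictions
  are provably permutation-invariant (tested); on discrete inputs the
  tie-break is at least deterministic and documented.
* **k selection.** Stratified 5-fold cross-validation over the 60 odd
  values k = 1, 3, …, 119 — odd k avoids 50:50 neighbour votes; 60 values
  give a wide, reproducible search. The criterion is mean validation
  accuracy at threshold 0.5; ties go to the smallest k. Grid values
  exceeding the smallest fold are dropped rather than erroring.
* **Rebalancing** applies to the training partition only: oversampling
  duplicates minority rows with replacement until parity (all original
  rows retained), subsampling draws majority rows without replacement down
  to the minority count. Both end exactly 50:50. The test partition always
  keeps the natural prevalence.
* **Threshold.** `prob >= t` calls a case. The inclusive boundary matters
  because KNN probabilities are discrete multiples of 1/k; inclusivity
  favours sensitivity at a tuned cut-off such as 0.42.

## Evaluation

Sensitivity, specificity, accuracy, precision and F1 come from the
confusion matrix; ratios with zero denominators are reported as `NaN` with
a warning rather than silently coerced. The ROC sweeps every distinct
probability as a threshold under the same `>=` rule, and the AUC is the
trapezoid area — which, for this construction, equals the tie-corrected
concordance probability (Mann-Whitney with half credit for ties). The
identity is asserted against a brute-force pair-enumeration oracle to
1e-10 in the tests; with heavily tied KNN probabilities a naive
unique-threshold sweep and the U-statistic genuinely disagree, which is
why the tie-corrected definition is fixed here. The default threshold
sweep uses every multiple of 0.01 in [0, 1]. Threshold selection offers
Youden's J and the constrained policy (smallest threshold whose
specificity clears a floor, which maximizes sensitivity subject to it).

## The inferential battery

Numeric predictors: Welch's t (unequal variances, Welch–Satterthwaite
degrees of freedom) and Hedges' g with pooled n−1 SD and the small-sample
correction `J = 1 - 3/(4(nx + ny) - 9)`; the sign convention is case minus
control, so a predictor that is *lower* in cases gets a negative g.
Categorical predictors: Pearson chi-square without continuity correction
(a `correct` flag exists) and Cramér's V. Per-APOE-group tests are
goodness-of-fit tests of each group's case/control split against the
cohort-wide proportions — the construction that directly asks "does this
risk group deviate from the overall pattern?". Raw p-values are reported;
no multiplicity adjustment is applied by default. Identical constant
groups return t = 0, p = 1; a zero pooled SD or a zero table margin is an
error.

## The synthetic cohort generator

`simulate_cohort()` is a liability-threshold model: genotypes are
binomial(2, MAF) under Hardy–Weinberg with no linkage disequilibrium, APOE
diplotypes arise from random mating over European-like haplotype
frequencies (ε2 0.08, ε3 0.78, ε4 0.14), and a latent liability

```
L = w_score * z + w_apoe * code + w_age * age_std + w_diabetes * diab
    + w_chol * chol_std + w_sex * sex + w_smoker * smoke + N(0, noise_sd)
```

labels the top `prevalence` quantile of the source population as cases;
the generator oversamples the source population until the requested case
and control counts are reached. Ages are uniform on [60, 99] (the
recruitment window); cholesterol is Normal(5.7, 1.1) mmol/L — a plausible
elderly-cohort placeholder, not an estimate; diabetes, smoking and sex are
Bernoulli(0.10/0.30/0.45). Missingness is injected completely at random
(the default rate is 5%, inside the realistic 1–10% band).

The default weights (`w_score = 0.48`, `w_apoe = 0.73`, `w_age = 0.35`,
`w_diabetes = 0.55`, `w_cholesterol = -0.064`, sex and smoking 0,
`noise_sd = 0.62`) were fixed once, by a grid search during development,
so that a large simulated cohort reproduces the effect-size landscape the
analysis expects: a strong score effect, a slightly weaker age effect, a
medium APOE association, a small diabetes association, a small *negative*
cholesterol effect, and null sex/smoking. They are deliberate constants,
not estimates of any population.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: linkage disequilibrium between SNPs,
population stratification and relatedness, informative (non-MCAR)
missingness, age- or sex-dependent covariate structure, measurement error
in phenotypes, and any real effect-size correlation between APOE and the
score panel. Results on synthetic cohorts validate the *machinery*, not
clinical performance.

## Reproducibility and problem sizes

Every stochastic operation is a pure function of its inputs and a seed.
Pipeline stages draw per-stage sub-seeds from the run's master seed via
`stage_seed()`, so switching the rebalancing strategy never perturbs the
train/test split — mirroring the design where the test set is constant
across rebalancing comparisons. Reports and manifests contain no
timestamps, so identical configuration and seed reproduce byte-identical
JSON output.

The test suite exercises the pipeline at sizes chosen to make stochastic
properties sharp while keeping the default run fast: exact oracles on
hundreds of random instances up to n = 200, and end-to-end stochastic
mirrors on cohorts of 1000 individuals by 379 SNPs over 20 seeds (null
calibration of the AUC, combined-versus-SNP-only signal recovery, and the
effect-size ordering).

## Known limitations

* Brute-force distance computation only; fine for cohorts up to ~10^4 but
  no KD-tree acceleration for larger ones.
* No distance-weighted voting, no multiclass support.
* No confidence intervals on AUC and no calibration curves.
* The VCF reader handles plain GT fields (phased or unphased, diploid);
  dosage (DS) fields and multi-allelic records are out of scope.
* Betas are consumed as given: no GWAS, no LD pruning, no re-selection of
  SNPs.
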