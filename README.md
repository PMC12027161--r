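# loadrisk

Risk prediction of late-onset Alzheimer's disease (LOAD) from common
genetic variation and routine clinical covariates, built as a tidyverse-style
R package. It is aimed at biostatisticians and genetic epidemiologists who
want a tested, reproducible implementation of a case/control KNN
classification pipeline over a polygenic risk score — including every step
around the classifier: genotype quality control, score standardization,
APOE diplotype calling, class rebalancing, threshold tuning, evaluation,
and the case-versus-control inferential battery — plus a synthetic cohort
generator so the whole pipeline is testable without access to
individual-level biobank data.

## The model

**Polygenic score.** Each individual's raw score is a weighted sum over
risk SNPs,

    score_raw = Σ_i (g_i + 1) · β_i

where `g_i ∈ {0, 1, 2}` is the risk-oriented dosage at SNP *i* (the
effect-allele count when `β_i ≥ 0`, its flip `2 − dosage` with `|β_i|` when
`β_i < 0`, so `g_i + 1` codes protective homozygote / heterozygote / risk
homozygote as 1/2/3) and `β_i` is the GWAS effect size. Scores are
standardized against the control group:

    z = (score_raw − μ_control) / σ_control

so controls have mean 0 and SD 1, and the `+ 1` offset provably never
changes a z-score (tested to 1e-12).

**APOE.** The ε2/ε3/ε4 haplotypes of rs429358 and rs7412 are called from
unphased C-allele counts and encoded ordinally by conferred risk:
ε2/ε2, ε2/ε3 → −1; ε3/ε3 → 0; ε2/ε4, ε3/ε4 → 1; ε4/ε4 → 2.

**Classifier.** A from-scratch k-nearest-neighbours classifier (Euclidean,
Manhattan or cosine distance) whose case probability is the case fraction
among the k nearest training rows; k is chosen by stratified 5-fold
cross-validation over 60 candidate values, the training set may be
rebalanced to 50:50 by oversampling or subsampling, and the decision
threshold (`prob ≥ t → case`) is tunable — lowering it trades specificity
for sensitivity, the quantity of clinical interest for early screening.

**Quality control.** SNPs with zero variance, missing rate > 10% or
MAF < 0.01, and individuals with > 10% missing genotypes, are excluded
(strict thresholds; boundary values survive), SNPs first, in one pass.

**Statistics.** Welch's t-test and Hedges' g for numeric predictors;
chi-square independence and Cramér's V for categorical ones, plus
per-APOE-group goodness-of-fit tests against the cohort-wide case/control
proportions.

## Worked example

Simulate the default cohort (1000 individuals, 23% cases, 379 risk SNPs,
a liability-threshold disease model with a realistic effect landscape),
then run the seven-model experiment grid:

```r
library(loadrisk)

sumstats <- simulate_summary_stats(n_snps = 379, seed = 42)
cohort   <- simulate_cohort(sim_params(seed = 1), sumstats)

runs <- run_model_grid(cohort, default_model_grid(), seed = 1)
summarise_runs(runs) |>
  dplyr::select(model_id, feature_set, sampling, metric, threshold,
                sensitivity, specificity, auc)
```

A run with `Rscript scripts/acceptance.R --seed 1` prints (cohort seeds
differ slightly from the snippet above):

```
  model_id feature_set sampling   metric    threshold sensitivity specificity   auc
1        1 snps_only   none       euclidean      0.5        0           1     0.536
2        2 snps_only   oversample euclidean      0.5        0.246       0.749 0.498
3        3 snps_only   subsample  euclidean      0.5        0.551       0.437 0.507
4        4 snps_only   subsample  manhattan      0.5        0.681       0.372 0.515
5        5 snps_only   subsample  cosine         0.5        0.580       0.528 0.582
6        6 combined    subsample  euclidean      0.5        0.783       0.706 0.838
7        7 combined    subsample  euclidean      0.42       0.928       0.537 0.838
```

Reading this: with no rebalancing (model 1) the classifier collapses onto
the majority class (sensitivity 0, specificity 1); per-SNP features alone
carry little signal at this cohort size because the polygenic signal is
spread across 379 weakly weighted SNPs; combining the standardized score
with APOE and the clinical covariates (model 6) recovers it
(sensitivity 0.78, specificity 0.71); and lowering the threshold to 0.42
(model 7) raises sensitivity to 0.93 at the cost of specificity — the AUC,
which is threshold-free, is unchanged.

The cohort-level statistics on the same run show the planted effect
landscape the generator emulates:

```
  variable    type        statistic  p_value  effect effect_type
1 z_score     numeric        10.5    4.9e-23  0.765  hedges_g
2 age         numeric         9.98   4.8e-21  0.734  hedges_g
3 cholesterol numeric         0.206  0.84     0.016  hedges_g
4 apoe        categorical   152      1.1e-32  0.390  cramers_v
5 sex         categorical     0.168  0.68     0.013  cramers_v
6 smoker      categorical     0.249  0.62     0.016  cramers_v
7 diabetes    categorical    26.7    2.4e-07  0.163  cramers_v
```

Each result type has `tidy()`, `glance()` and `autoplot()` methods:
`autoplot(runs[["6"]]$eval)` draws the ROC curve and
`autoplot(runs[["6"]]$sweep)` the sensitivity/specificity threshold sweep.

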