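---
title: "Stacked ensemble early detection from pre-diagnostic serum panels: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble early detection from pre-diagnostic serum panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`serostack` builds multi-marker early-detection classifiers for nested
case-control serum cohorts with time-to-diagnosis (YTD) structure. This
vignette is the package's account of the statistics it implements, the
defaults it chose where the design was genuinely open, and what its tests do
and do not demonstrate.

## The data model

One row per serum sample: subject and sample identifiers, case/control
status, months from draw to diagnosis (cases only in a discovery design),
marker concentrations, and clinical covariates (age at draw, BMI, HRT use,
OCP ever-use, diabetes, sex). Values below an assay's limit of detection are
carried as flags — never silently as numbers — until `impute_low()` resolves
them, by default to half the marker's minimum observed value (the
substitution rule is not fixed by the study design; half-minimum is the
common practice for left-censored assay panels, and a fixed floor is
available).

Case samples map to single YTD groups 0-1, 1-2, 2-3, 3-4 and 4+ years.
Intervals are half-open `[a, b)`: a draw exactly 24 months before diagnosis
belongs to 2-3. The boundary convention is ours — the underlying study never
states one — and a dedicated boundary test pins it. Joined group `0-k` is
the union of the first `k` single groups. Controls carry no YTD and are
eligible for every group; every group evaluation therefore uses that group's
cases against *all* controls unless a per-group control allocation is
supplied (the study's own per-group control table is not public).

`stratified_split()` reproduces the 2/3 : 1/3 design split, stratifying on
age quartile, BMI quartile, HRT, OCP, diabetes, status and single
time-group. Quartiles are computed on the full table before splitting, ties
falling to the lower quartile. Fully crossing those keys shatters a
~470-sample table into mostly singleton strata, which silently inflates the
training fraction and unbalances the class ratio; rare strata are therefore
collapsed hierarchically (full keys → status × time-group → status) before
the per-stratum `round(frac × n)` allocation. Strata of size one go to
train. Longitudinal samples from one subject are split independently by
default, mirroring the source design's "all samples independent" stance; see
the leakage note below for why `by_subject = TRUE` exists.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. Its defaults
are the study conditions: 143 case subjects contributing 218 case samples
(35 subjects with 2-6 annual draws — the extra draws are distributed
structurally so the totals hold exactly), 249 controls, 101 markers, age
62.5 ± 6 years with a +2.46-year case shift, BMI 26.6 ± 4 with +0.8, and
binary covariates drawn so that the case/control odds ratios are 0.41 (HRT),
1.47 (OCP) and 4.99 (diabetes) in expectation, at the control prevalences
implied by the published counts.

Marker `m` is log-normal; a case sample drawn `t` years before diagnosis has
its log-mean shifted by `delta_m * exp(-t / tau_m)`. The exponential rise
toward diagnosis is the simplest kinetic shape consistent with markers whose
case/control separation grows as diagnosis approaches; the source fits no
kinetic model, so `delta` and `tau` are placeholders for property tests, not
estimates. Default informative markers (CA19_9, MUC16, THBS2, CEACAM5, VWF,
IL6ST with `delta` 2.0 … 0.6 and `tau` 2-4 years) make the canonical panel
discoverable at cohort scale. Markers share a Gaussian-copula
equicorrelation of 0.2 so ensemble diversity is non-trivial; per-marker
censoring at the 5% control quantile produces below-LOD flags. Baseline
log-means derive from the *config* seed, not the draw seed, so an external
set simulated from the same config shares marker scales and trained
signatures transfer.

What the generator does **not** emulate: assay plate effects and dilution
CVs, subject-level marker random effects (draws from one subject are
conditionally independent), Lewis-negative CA19-9 non-expressors, and any
real inter-marker covariance structure. Passing tests on this generator show
the pipeline's statistical machinery is correct and calibrated — they do not
certify performance on real serum panels.

## Firth logistic regression

`firth_glm()` maximizes the Jeffreys-prior penalized log-likelihood
`l(beta) + 0.5 * log det I(beta)` with modified-score Newton steps and
step-halving, keeping estimates finite under complete separation and zero
cells; for a saturated one-binary-covariate design the result equals the
`(a+1/2)(d+1/2)/((b+1/2)(c+1/2))` half-cell odds ratio, which the tests use
as a closed-form oracle. P-values are penalized likelihood-ratio tests (the
coefficient profiled to zero, the penalty always computed on the full
design); Wald is available but not default. Confidence intervals solve the
profile penalized likelihood at the chi-square(1) 0.95 cutoff by bisection
bracketed at `beta ± 10 SE` (widened geometrically if needed), tolerant of
likelihood-degenerate tails. Convergence demands a standardized score
(`score_j * SE_j`) and step below 1e-6 within 100 iterations: the
standardization makes the criterion invariant to covariate scale, and the
cap reflects that step-halving can make convergence linear on heavy-tailed
markers (~55 iterations observed). Continuous covariates are *not*
standardized before fitting — odds ratios are per natural unit.
`rank_features()` runs one univariate fit per feature and orders by
p-value, ties broken by name; failed fits are kept as `NA` ranks with a
warning rather than aborting a scan.

## Base learners, resampling and search

Ten families cover boosting, kernel methods, forests, networks and linear
models: boosted classification trees and bagged adaptive boosting (an
in-package AdaBoost.M1 over `rpart` trees — no installed library provides
these families), RBF-kernel SVM (`e1071`, with in-package Platt calibration
of the decision values because libsvm's internal probability CV is not
reproducible within a session), random forest (`ranger`), PCA-extracted
neural network (`nnet`), Gaussian process with RBF kernel (`kernlab`),
elastic-net logistic (`glmnet`), gradient-boosted trees (`xgboost`),
stepwise-AIC logistic (`MASS`), and Gaussian naive Bayes (`e1071`).

Training follows repeated stratified k-fold CV with minority oversampling
applied *only inside training folds* — a memorization test (a deep forest on
pure noise) verifies the out-of-fold probabilities cannot leak. Random
hyperparameter search draws from ranges shipped as data
(`inst/extdata/learners.yaml`); the reference design used 1000 draws and
5 × 10-fold CV, which is configurable, while package defaults are
desk-scale. Out-of-fold probabilities are averaged across repeats (the
alternative — concatenation — is not what a stack can consume at prediction
time) and clipped to `[1e-6, 1 - 1e-6]` so the geometric-mean stack is
always defined. A fold a family cannot fit scores AUC 0.5 with a warning.
`scan_feature_space()` walks the Firth ranking in increments of 10 and
returns the smallest panel achieving the best cross-validated AUC; the scan
objective is the stacked CV AUC (the wording of the source is ambiguous
between per-learner and stacked objectives; the stacked one is implemented).
`bruteforce_combo_scan()` provides the up-to-3-marker plain-logistic
baseline.

## Stacking

The BMA stack fits logistic regressions on subsets of the base-learner
probability columns, scores them by BIC, weights by
`exp(-deltaBIC / 2)` and prunes with Occam's window at odds 20 (the
reference implementation's default; configurable). Enumeration is exhaustive
up to 12 columns — covering the 10-column JTG2L and 5-column STG3L cases —
and falls back to collecting forward plus backward stepwise BIC paths for
wider matrices (STG2L's 50 columns); a branch-and-bound on a least-squares
approximation would be the classical alternative, but no installed backend
provides it and the stepwise path is the standard approximation. Inputs
enter on the probability scale, not the logit scale. MEAN, GEOMEAN and MAX
stacks are parameter-free row-wise pools and always satisfy
`GEOMEAN <= MEAN <= MAX`; AVNNET (five averaged single-hidden-layer
networks, 5 units — sizes are ours, only the method is named by the source)
is permitted for STG2L.

Architectures: JTG2L trains the 10 learners on one joined group and stacks
their out-of-fold columns. STG2L trains 10 learners per single group; the
stack matrix over all training samples uses out-of-fold values where a
sample was in that group's training table and plain model predictions
elsewhere (the model never saw those samples), so no entry is scored by a
model trained on it. STG3L stacks each group's learners with BMA first and
the resulting G columns again. Meta-level CV (`meta_cv_auc()`) refits the
stack per fold; the reference design is 10 × 10-fold, and tests run reduced
plans (e.g. 2 × 5) — a choice of problem size, stated here once.

## Evaluation

AUC is the midrank Mann-Whitney statistic (ties count 1/2), cross-checked
against brute-force pair counting. CIs are stratified-bootstrap percentile
intervals (cases and controls resampled separately; default 2000
replicates); intervals crossing 0.5 are flagged insignificant. ROC curves
are compared by a paired stratified bootstrap of the AUC difference with a
normal reference; zero bootstrap variance is guarded to p = 1. Operating
points maximize sensitivity subject to specificity >= 0.90 on the
evaluation set (matching the reporting style of the source; a
train-derived-threshold mode is the honest prospective alternative and both
are exposed); among ties the higher-specificity cutoff wins, samples are
called positive strictly above the threshold, and MCC is 0 when a marginal
factor vanishes. The cross-time-group matrix evaluates each joined-group
model on each joined evaluation group (that group's cases, all controls).
`prevalence_rescan()` down-samples one class to a target prevalence and
checks the replicates against the analytic
`PPV(p) = sens * p / (sens * p + (1 - spec)(1 - p))`. `pairwise_kappa()`
dichotomizes each learner at its own 90%-specificity threshold and reports
Cohen's kappa as the ensemble-diversity summary.

## Importance and external validation

`firm_importance()` is the variability of the partial-dependence function:
the model's mean predicted probability over a 20-point quantile grid of the
feature (both levels for binaries), with all other features at their
observed values; the raw importance is the standard deviation over the grid
(half-range for binaries), computed on the training set with a seeded
2000-row cap on the background sample. Within each (learner, group) cell raw
values are scaled by the cell maximum; the summary is the per-feature median
across cells. A closed-form linear-logistic oracle pins the ordering
(|coefficient| × sd of feature).

`marginal_validate()` scores a frozen model on an external cohort in which
HRT/OCP were never collected: each of `n_rand` replicates draws the missing
yes/no covariates for women (Bernoulli at the discovery-set control
frequencies 48/249 and 127/249 by default, or uniform 0.5) and fixes "no"
for men, then the full metric set is computed per replicate; medians, IQRs
and a bootstrap mean-with-CI summarize the marginal performance. A model
whose panel excludes the randomized covariates shows exactly zero
dispersion.

## A leakage finding worth knowing about

With longitudinal case subjects and the default sample-level split, samples
of one subject land on both sides of the split carrying identical age, BMI
and covariate values. Those act as subject fingerprints: on a *null* cohort
(no marker effects, unit covariate odds ratios) the stacked pipeline's test
AUC averages ~0.54 rather than 0.50 purely through subject re-identification
— train a model on one draw of a case subject, recognize the other draw in
the test set. The package exposes `by_subject = TRUE` in
`stratified_split()` to close this path; the null-calibration test uses
independent samples so that it measures bootstrap-CI calibration rather than
this artifact. Users analyzing real longitudinal panels should treat
sample-level splits of repeated draws with suspicion.

## Problem sizes used by the tests

Unit and acceptance tests run at desk scale, as the package's own choice of
problem size: cohorts of 150 cases / 250 controls (the calibration and
recovery suites), 2-3-fold single-repeat base CV with 1-2 random draws,
200-500 bootstrap replicates, and importance grids of 8-10 points over
120-150 background rows. The full-scale settings of the reference design
(5 × 10-fold base CV, 1000-draw search, 10 × 10-fold meta CV, 2000
bootstrap replicates, 1000 external randomizations) are all reachable
through the same arguments.

## Known limitations

- The BMA stack's stepwise candidate search above 12 columns explores a
  path, not the full model space; weights are conditional on the visited
  set.
- Operating thresholds set on the evaluation set reproduce the source's
  reporting but are optimistic for prospective use; the train-derived mode
  should be preferred in deployment.
- The generator's independence of draws within a subject understates
  within-subject correlation of real serial samples, which makes the
  leakage finding above conservative if anything.
- Mixed time-group combinations (e.g. 0-1 plus 1-4) are deliberately not
  implemented; the source reports them as underperforming.
- No SMOTE-style synthetic augmentation and no pathway-enrichment step; both
  are outside this package's scope.
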