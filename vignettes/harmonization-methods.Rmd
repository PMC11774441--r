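---
title: "Harmonizing radiomic features of benign and malignant nodules: methods and design"
author: "opncb package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing radiomic features of benign and malignant nodules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opncb)
```

## The problem

Radiomic features — quantitative intensity, shape and texture summaries of
a segmented lesion on CT — depend not only on the underlying tissue but on
how the image was acquired. Contrast enhancement (CE), scanner
manufacturer, tube voltage (KVP) and focal spot size all leave measurable
imprints on the feature values. A malignancy classifier trained on
clinically acquired scans therefore risks learning acquisition protocol
rather than biology, and CE makes the risk acute: contrast is ordered when
there is already cause for concern, so CE is quasi-systematically
confounded with malignancy. A classifier that "detects CE" looks accurate
and transfers nowhere.

ComBat harmonization addresses this by modelling, per feature, an additive
location offset and a multiplicative scale factor for each *instance*
(level) of an acquisition parameter, shrinking the per-instance estimates
towards a common prior by empirical Bayes, and removing them. The open
question this package is built around: when the cohort mixes benign and
malignant tissue — which may respond *differently* to the same protocol —
should ComBat be fitted on everything at once (*collective*), on
everything with the biological subgroup as a preserved covariate
(*covariate*), or on each subgroup separately (*separate*)?

## The model

For scan $j$ in batch (instance) $i$ and feature $g$, ComBat assumes

$$ y_{ijg} = \alpha_g + X_j \beta_g + \gamma_{ig} + \delta_{ig}\,\varepsilon_{ijg},
\qquad \varepsilon_{ijg} \sim N(0, \sigma_g^2). $$

Estimation follows the standard parametric ComBat recipe: least squares
for $\alpha$, $\beta$ and the per-batch offsets under the constraint
$\sum_i n_i \hat\gamma_{ig} = 0$, with $\hat\sigma_g^2$ the pooled
residual variance (denominator $N$); standardization
$z = (y - \hat\alpha - X\hat\beta)/\hat\sigma$; then empirical-Bayes
shrinkage of each batch's location and scale with method-of-moments
hyperparameters (Normal prior on $\gamma$, inverse-gamma on $\delta^2$),
iterating the conditional posterior updates until the maximum relative
change falls below $10^{-4}$ (cap 500 iterations — the fit converges in a
handful of steps on continuous data). Harmonized values are
$\hat\sigma_g (z - \gamma^*_{ig})/\sqrt{\delta^*_{ig}} + \hat\alpha_g + X_j\hat\beta_g$.
The test suite verifies that this implementation agrees with the
independent reference implementation in the `sva` package to within
$10^{-6}$ relative on both collective and covariate fits.

The covariate is the 3-level subgroup (benign / malignant / screening),
one-hot encoded against the most frequent level; the encoding choice does
not affect the harmonized values. Only categorical covariates are
supported. There is no reference-batch or mean-only mode. Features that
are constant within some batch level cannot be standardized; they are
passed through unchanged with a warning rather than aborting the fit.
With a single feature the method-of-moments hyperparameters are undefined
and the fit falls back to the unshrunk per-batch estimates.

### Nested harmonization and permutation ordering

Several acquisition parameters are corrected sequentially: the table
harmonized for parameter 1 is the input to the fit for parameter 2, and
so on. Because the outcome depends on the order, `optimizePermutation()`
fits a plan for every permutation of the parameters (4 parameters = 24
permutations, enumerated exhaustively — no heuristic search) and keeps
the one leaving the most features acquisition-independent under the
Kruskal-Wallis gate described below, at the same $\alpha$ as the final
analysis. Ties are broken deterministically in favour of the earliest
permutation in lexicographic order of parameter names. In separate mode,
each of the three subgroups gets its own model per parameter, and the
screening subgroup is a fitting scope of its own even though the gate
only tests benign and malignant scans.

Fit-on-train / apply-to-unseen semantics are strict: a plan stores every
fitted model and transforms new scans without refitting; test scans are
routed through the models of their own subgroup in separate mode, in the
order chosen on the training set. Two exclusion rules keep the fits
well-posed: training scans in a (parameter, instance) cell — per
subgroup, in separate mode — with fewer than `minBatchSize` scans are
dropped (iterating until stable), and test scans carrying an instance
never seen in the surviving training scope are dropped. `minBatchSize`
defaults to 3: scale estimation needs replicates, and two scans per cell
is exactly the configuration known to break the fit. Exclusion is
computed once per trial under the strictest (separate-mode) scoping so
that all methods see identical training and test sets.

### The acquisition-independence gate

After harmonization, each feature is tested per acquisition parameter
within the benign subgroup and within the malignant subgroup by the
Kruskal-Wallis rank test over the parameter's instances (midranks,
standard tie correction, chi-square approximation on $k-1$ degrees of
freedom). A feature is *acquisition-independent* iff no test over any
parameter in either subgroup has $p \le 0.05$; there is deliberately no
multiple-testing correction — the gate is a conservative filter, not an
inference. Cells with a single instance present are untestable, logged,
and counted as passes (they cannot exhibit dependence). The screening
subgroup is not gated on: its scans mix unknown biology, so distribution
differences there are not evidence of failed harmonization.

Two numerical notes. First, the gate's statistic is computed in a batched
form across all features at a fixed grouping (the permutation search
evaluates ~20,000 tests per mode and trial); the test suite asserts exact
agreement with `stats::kruskal.test`. Second, the chi-square tail is an
approximation: at the group sizes the gate actually sees (dozens of scans
per subgroup) it tracks the exact permutation distribution closely, but
at toy sizes ($N \le 20$) it can deviate from full-enumeration exact
p-values by far more than intuition suggests — the test suite documents
this by enumeration. Exact enumeration is kept as a test oracle only; the
production path always uses the chi-square form, matching standard
practice.

### The predictive pipeline

Acquisition-independent features enter a LASSO (L1-penalized least
squares on the 0/1 malignancy label, penalty $\alpha = 0.05$ in the
$\tfrac{1}{2n}\mathrm{RSS} + \alpha\lVert\beta\rVert_1$ parameterization
— glmnet's `lambda`; features are z-scored on training statistics first,
otherwise a single penalty across features is meaningless). Features with
nonzero coefficients train a soft-margin linear SVM (hinge loss,
$C = 1$, again on training-standardized features, unweighted classes).
Decision scores are signed distances to the hyperplane with the threshold
fixed at 0; no probability calibration. The regression (not logistic)
form of the LASSO is the default; both hyperparameters are exposed.

When the gate plus LASSO leave nothing — which happens systematically for
collectively harmonized data with subgroup-specific effects — the model
degenerates to a constant benign predictor: sensitivity 0, specificity
100, balanced accuracy 50. This fallback is a first-class outcome: the
evaluation harness records it, excludes such trials from that method's
mean prediction metrics, and reports the fallback rate.

### Evaluation harness

`runExperiment()` repeats stratified 5-fold cross-validation (stratified
on subgroup crossed with malignancy label; default 10 repeats = 50
trials) and, per trial and method: exclusion, permutation-optimized
nested harmonization on the training scans, gating, LASSO, SVM, then
application of the frozen plan and model to the unseen test scans.
Metrics (sensitivity, specificity, balanced accuracy, rank-statistic
ROC-AUC) are computed overall and on the screening subgroup alone — the
clinically interesting scope, since those scans had unknown diagnoses.
Splitting is at scan level, mirroring the emulated study design; note
that patients with repeat scans can therefore appear on both sides of a
split, an acknowledged source of optimism for absolute metrics (the
comparison *between* methods, which shares splits, is unaffected).

Per-trial AUC pairs are compared with the paired DeLong test
(placement-value structural components, normal approximation), and
p-values are Holm-Bonferroni-adjusted across trials within each method
pair. Aggregates are means with 95% t-intervals across usable trials.
The permutation is re-optimized in every trial, since it is a property
of the training set. A label-shuffle mutation test in the suite verifies
the absence of train/test leakage: permuting test labels changes no
fitted object and no test score.

`uniformGroupCheck()` implements the calibration control: among scans
sharing *every* acquisition-parameter instance, a k-fold train/test
Kruskal-Wallis comparison per feature and subgroup should be null, so
the non-significant fraction should sit near $1-\alpha$. One caveat
found while validating it: because random folds share the distribution
of any *hidden* acquisition factor, this check stays calibrated even
when the schema is incomplete — a deficit should not be over-read, and
with very small folds the test is conservative rather than anticonservative.

## The synthetic cohort generator

No clinical feature table is distributed, so `simulateCohort()` generates
cohorts whose *statistical* structure matches the setting the methods are
designed for, with fully known ground truth. The default geometry copies
the emulated study: 567 scans of 305 nodules from 193 patients, split 58
benign / 186 malignant / 323 screening scans, with repeat scans per
nodule following a truncated geometric law (mean 567/305 ≈ 1.9).
Within-subgroup patient/nodule allocations are adjusted so that counts
nest cleanly (the clinical tabulation double-counts screening patients
whose nodules later turned malignant); the overall totals and the scan
split are preserved exactly. A fraction 0.076 of screening nodules is
flagged later-malignant; their scans carry label 1 but only half the
malignancy shift (`lcsAttenuation = 0.5`), reflecting that their status
at scan time was unknown.

Feature values are Gaussian: $y = \mu_g + \kappa_g s + \sigma_g
\varepsilon$, with $s \in \{0, \tfrac12, 1\}$ the malignancy signal and
batch effects injected as $y \leftarrow \mu\text{-part} + \sum_p
\gamma_{p,i,s,g} + \prod_p \delta_{p,i,s,g}\,\varepsilon\text{-part}$ —
additive locations, multiplicative scales, order-independent by
construction. This is exactly the model family under which ComBat's
assumptions hold, which is the point: the generator isolates the
*comparison between harmonization strategies* from questions of model
misspecification. Consequences for interpretation: passing tests show the
pipeline does what it claims under Gaussian location/scale effects; they
do not show robustness to heavy-tailed features, nonlinear acquisition
effects, or realistic radiomic correlation structure (an equicorrelation
knob, default 0 in `simulationConfig()`, is the only concession).

`cohortConfig()` fixes the study conditions used throughout the tests and
the acceptance script; all values were chosen once, as a plausible
radiomics setting, before any acceptance measurement:

* **Schema**: CE (no/yes), manufacturer (3 vendors), KVP (100/120), focal
  spot (small/large).
* **CE-malignancy confounding**: P(CE = yes) = 0.85 for malignant scans,
  0.25 for benign, 0.10 for screening — the diagnostic-vs-screening
  asymmetry described for clinical practice.
* **Biology**: every feature shifts with malignancy (1.2 SD for 20
  "strong" features, 0.8 SD for the rest) and the noise is equicorrelated
  at 0.4, yielding moderate class separability rather than a trivially
  separable cohort.
* **Batch effects**: location magnitudes 1.5 / 0.8 / 0.6 / 0.7 SD for
  CE / manufacturer / KVP / focal spot (CE strongest), modulated per
  feature by a fixed weight in [0.6, 1.4]; scale factors up to 1.3.
* **Scenarios**: `"shared"` applies identical effects in all subgroups
  (the regime where a covariate fit is exactly right); `"divergent"`
  gives 60% of the features subgroup-specific effects — opposite sign in
  benign vs malignant tissue, half strength in screening scans — the
  regime the separate strategy exists for; `"none"` is the null.

## Problem sizes and determinism

Unit tests run the full pipeline on cohorts of 567 scans with 12-40
features, and statistical checks at the sample sizes their tolerances
require (up to 10,000 scans for moment-matching oracles). The
acceptance-style comparisons use the complete 107-feature, 4-parameter,
567-scan cohort with 5-fold x 2-repeat cross-validation (10 trials) and
exhaustive 24-permutation optimization per trial and mode. Every source
of randomness flows from one root seed through derived child streams;
identical seeds give byte-identical cohorts, splits, plans and reports.

## Known limitations

* Gaussian, (near-)independent features with additive/multiplicative
  acquisition effects are an idealization; real radiomic features are
  correlated blocks with skewed marginals.
* Scan-level splitting leaks patients across folds (mirroring the
  emulated design); grouped splitting would lower absolute metrics.
* The training-set gate is evaluated in-sample: separate-mode fitting
  zeroes each subgroup's batch means on the very scans the gate then
  tests, so its pass fraction is structurally higher than an
  out-of-sample evaluation would give. The covariate mode, whose
  corrections are estimated on the pooled cohort, faces ordinary null
  sampling noise across 8 tests per feature and caps well below 100%
  even when its assumptions hold exactly. Comparisons between modes
  should be read with this asymmetry in mind.
* The DeLong test treats scans as independent; repeat scans of one
  nodule violate this mildly (a clustered variant is out of scope).
* Parametric EB priors only; no nonparametric, longitudinal or GAM
  variants.
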