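---
title: "Auditing confounding in image-based disease classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing confounding in image-based disease classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(confaudit)
```

## The question the pipeline answers

When an image classifier predicts a disease on an observational cohort,
how much of its performance is disease signal in the pixels, and how much
is routed through everything *else* that is correlated with the label —
who the patient is and how the hospital handled them? `confaudit`
operationalizes the audit: hold the model fixed, rebuild the test set so
that covariate–disease associations are removed by case–control matching,
and watch what happens to the AUC. Performance that survives matching is
direct signal; performance that collapses was confounding.

## The generative model

`simulate_cohort()` draws from an explicit structural-causal model, so
every claim about "what the pixels can know" is checkable by
construction.

**Patient traits (PT).** Age (truncated normal, mean 62, SD 22), sex
(65% F), BMI (normal around `29 − 0.04·(age−60)`, SD 6, floored at 14,
with a 0.2% rate of implausible data-entry values that the feasibility
filter later removes), and two symptom flags: fall
(`plogis(−1.75 + 0.035·(age−60))`) and pain (~50%).

**Fracture.** A patient-level logistic model on PT:
`logit P = α + 0.40·(age−60)/10 + 0.10·[F] + 0.45·(25−BMI)/5 +
0.80·fall − 0.70·pain`. Signs follow hip-fracture epidemiology (older,
thinner, post-fall patients at higher risk; pain is a non-specific
indication). The intercept `α` is calibrated by bisection against the
drawn PT distribution so that the radiograph-level prevalence equals the
configured 3%. Effect sizes are a design choice: they were fixed once so
that covariate-only classifiers land where observational hip-radiograph
studies put them (patient-only AUC ≈ 0.8, process-only ≈ 0.9), and not
revisited.

**Hospital process (HP).** Given fracture and PT, each radiograph is
triaged: order priority (`+2.2` log-odds for fracture), department
(fracture and falls route to the ED), scanner (department fleet mix, a
portable-unit shift of `+2.0` for fracture, and a year drift as units are
phased in and out), view (suspected fractures get dedicated unilateral
and frog-leg views), order datetime (mild weekend excess for fractures),
technician and radiologist pools by department, radiation dose
(scanner calibration × body habitus), and three log-normal latency
intervals shortened for stat orders. The latency tails deliberately land
a small fraction of values outside the feasible [1 min, 1 day] window so
the cleaning rules have something to clean.

**Pixels.** `render_image()` composes designed signatures, not anatomy:
a fixed pelvis-like base pattern; per-scanner collimation border,
contrast, offset and noise grain; a view-dependent side marker; BMI
brightness and soft-tissue mottle; age-dependent bone-pattern contrast
(an osteopenia analogue that saturates above ~70 y); dose-dependent
quantum noise; and, when `beta_direct > 0`, a 3-px diagonal line in the
femoral-neck region with contrast `beta_direct`. At `beta_direct = 0`
(the default) the pixels are a function of (PT, HP) only — conditional
independence from the label is exact, so the audit has a known ground
truth. Per-image RNG streams are seeded by a hash of the global seed and
`image_id`, making cohorts byte-reproducible regardless of rendering
order.

**Scale.** The default is 4,000 patients at ~2.6 radiographs each
(~10,400 images, 3:1 patient-stratified train:test, ~80 test cases). This
is a deliberate compromise: large enough that the matched cohorts and the
multimodal-vs-ensemble comparison are not noise-dominated, small enough
that a 20-seed experiment runs in minutes on one CPU. The acceptance
script uses 9,000 patients (>20,000 radiographs) for the prevalence
check, mirroring the scale of the real cohorts this design emulates.

## What the pixel calibration does and does not claim

Two renderer parameters were set against the qualitative pattern expected
of a generic image embedding rather than left arbitrary. The BMI strength
(0.3) puts the image-readability of BMI near AUC 0.75–0.8; an earlier,
stronger setting made BMI nearly perfectly readable (AUC 0.91), which is
unrealistic and let tiny post-matching BMI gaps keep the matched AUC
above chance. The age pathway saturates in the elderly range so that two
75- and 68-year-old matched records look alike, while the full training
age range (18–100) still makes age learnable. These are fidelity choices
about the *generator*, not tuning of any test threshold, and they are
frozen.

## Tabular preparation

* `filter_infeasible()`: latencies outside [1, 1440] minutes and BMI > 60
  become `NA`; nothing else is touched.
* `consolidate_nominal()`: staff columns keep their 3 most common levels;
  the rest become `other_valid_entry`. Frequency ties at the cut keep the
  lexicographically smaller level, so results are deterministic; an
  existing `other_valid_entry` bucket passes through, making the rule
  idempotent.
* `binarize()`: continuous variables become indicators of exceeding the
  *training-partition* median (ties map to 0); day-of-week becomes
  weekend; view becomes bilateral-vs-lateral; other categoricals keep
  their two most common training levels (remainder `NA`). Medians and
  level choices are estimated on the training split only and reused on
  test — swapping partitions changes the fitted constants, which the
  tests assert as the no-leakage property.
* `impute()`: categorical `NA` becomes an explicit `"(Missing)"` level;
  missing BMI is predicted by a linear regression trained on
  complete-BMI training rows using all other PT + HP covariates
  (median fallback when the regression cannot score a row); other
  continuous gaps take the training median. Imputation feeds matching
  and the multimodal models; the single-variable screens instead drop
  `NA` rows, so missingness never manufactures associations.

## Imaging

The featurizer is a fixed filter bank: 8×8 grid-pooled means, pooled
standard deviations, and pooled horizontal/vertical absolute gradient
energies (256 dimensions; the inner loop is compiled, with a pure-R
reference kept for testing). It is not a CNN and does not pretend to be;
the audit's claims concern what a generic embedding captures — borders,
markers, grain, brightness — and those it captures well (scanner model is
predictable at AUC 1.00 from these features, as one would expect from
collimation borders alone). An adapter accepts an external featurizer so
a real penultimate-layer embedding can be dropped in.

Features are reduced to 10 principal components by exact SVD fit on the
training rows only (~80% of feature variance on default cohorts); test
rows are projected with the training loadings. `pc_covariate_r2()`
regresses each component on each covariate: on default cohorts the
scanner dominates PC1 (R² > 0.9), with view and age explaining later
components — the unsupervised signature of acquisition-driven variation.

## Models

Binary targets use ridge-regularized logistic regression over the grid
λ ∈ {0, 10⁻³, 10⁻², 10⁻¹, 1}, selected by 10-fold cross-validated AUC
with class-stratified folds; λ = 0 is refit as an exact MLE. The same CV
produces out-of-fold training scores, which the Naive Bayes ensemble
uses as its image evidence so the evidence density is estimated without
optimism. Continuous targets use least squares (minimum-norm fallback on
rank-deficient designs).

The Naive Bayes ensemble models a clinician integrating an image score
with chart data under an independence assumption: class-conditional
Gaussian-kernel densities (Silverman bandwidth per class) for continuous
predictors, Laplace-smoothed tables for categoricals, class-frequency
priors, product-rule posterior. Image probability scores enter on the
logit scale: kernel densities behave badly on a bounded, highly skewed
score (at 3% prevalence nearly all mass sits near 0), and the logit makes
the class-conditional score distributions near-Gaussian, preserving the
score's ranking when it is the only evidence.

## Matching

`match_controls()` downsamples the non-fracture test radiographs:
`random` takes one uniform control per case; the matched levels process
cases in seed-shuffled order and give each its minimum-Gower unused
control (greedy, without replacement), ties broken by smallest control
`image_id`. Gower dissimilarity averages range-normalized absolute
differences (continuous; ranges from the test partition, the pool being
matched from) and mismatch indicators (categorical), skipping missing
components and renormalizing; an all-missing pair is maximally unlike
(1). Distances use the raw-scale imputed covariates — the cohort tables
report continuous age/BMI means per cohort, which presumes raw-scale
matching. Matching variables: `demographics` = age + sex; `pt` = the five
patient traits; `pt_hp` adds every HP covariate known at acquisition time
(the reading radiologist and the interpretation latencies are
post-acquisition and excluded). A 1:1 ratio is fixed; if controls run
out, unmatched cases are logged, never silently dropped.

## Statistics

AUC uses midranks (ties get half credit) and is identical to the
Mann–Whitney statistic — asserted exhaustively for small inputs in the
tests. DeLong variance comes from the structural components; paired
comparisons use the component covariances, unpaired comparisons set the
covariance to zero and refer `z` to the normal (a well-known alternative
refers it to a t distribution; the tests pin our convention against the
alternative's statistic). Youden's point maximizes sensitivity +
specificity − 1 with ties broken toward higher sensitivity. Bootstrap
CIs are class-stratified percentile intervals. Fisher tests report the
conditional hypergeometric two-sided p with the *sample* odds ratio
`ad/bc` (0/∞ for zero cells) — not the conditional-MLE odds ratio —
because the association screen is descriptive.

## Numerical and degenerate-input choices

Constant images standardize to all-zeros with a warning. A zero Gower
range contributes 0 (all values equal). Degenerate zero-variance AUC
comparisons (e.g. two perfect classifiers) return p = 1 when the AUCs are
equal, 0 otherwise, with a warning. Separable logistic fits converge
under the ridge floor; collinear MLE designs fall back to the smallest
ridge. Kernel densities are floored at 10⁻³⁰⁰ before taking logs.
Single-class screen targets are skipped with a warning rather than
fitted.

## What passing tests show — and what they do not

The acceptance-style tests assert, over 20 fixed seeds under the default
conditions: (1) matched cohorts are exactly 50% prevalence; (2) with
`beta_direct = 0` the image-only model clears AUC 0.70 cross-sectionally
while its fully-matched AUC CI contains 0.5 in ≥80% of seeds; (3) with a
strong direct signature the cross-sectional and matched AUCs agree within
0.05; (4) NB(IMG, PT) sits between PT-only and multimodal IMG+PT in a
majority of seeds (at 12,000 patients the ordering is decisive:
0.790 / 0.842 / 0.874, paired p ≈ 10⁻⁹ and 10⁻⁵); (5) the count of
Fisher-significant covariates is non-increasing across
random → demographics → PT → PT+HP in a majority of seeds; plus exact
small-sample oracle identities and generator-recovery checks.

These results validate the *method* — that the pipeline detects
confounding when it is present by construction and clears a model that
has real signal. They do not show that any particular real-world
classifier is confounded: real radiographs have anatomy, real triage has
pathways no 14-variable model captures, real labels carry NLP noise, and
real CNN embeddings differ from a filter bank. The pipeline accepts
user-supplied cohorts (CSV metadata + PNG directory + an external
featurizer) precisely so the same audit can be run where it matters.

## Known limitations

* The renderer emits signatures, not anatomy; nothing about lesion
  morphology transfers.
* Greedy 1:1 Gower matching is not optimal matching; residual continuous
  imbalance of a few percent of range is typical, which is why the
  matched AUC hovers slightly above 0.5 rather than at it.
* The year drift is encoded only through the scanner mix, so year is
  image-predictable but weakly (held-out R² ≈ 0.02–0.1 by seed).
* Multiple-testing correction across the 19 covariate screens is
  deliberately absent; the monotone-count claim is about comparisons
  within a seed, not calibrated inference.
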