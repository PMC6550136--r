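# confaudit

Confounding audits for medical-imaging classifiers.

## The problem

Observational radiology cohorts are shaped by care delivery. Patients a
clinician suspects of hip fracture are older, thinner, have fallen, and —
because of triage — get imaged sooner, on particular scanners, in
particular departments, with "stat" orders. An image classifier trained on
such a cohort can therefore reach a respectable fracture AUC without ever
seeing a fracture line: scanner borders, side markers, noise grain and
soft-tissue brightness are all in the pixels and all associated with the
label. This *shortcut learning* is invisible to a conventional held-out
evaluation, because the held-out set carries the same confounding.

`confaudit` is an analysis pipeline that makes this failure measurable:

1. **Simulate** an observational radiograph cohort with an explicit causal
   structure — patient traits (PT: age, sex, BMI, fall, pain) drive
   fracture risk through a logistic model; fracture and PT drive
   hospital-process (HP) triage (department, scanner, order priority,
   view, timing, staff, dose); and HP/PT leave signatures in the rendered
   pixels. A dial, `beta_direct`, sets the contrast of a genuine fracture
   line; at `beta_direct = 0` the pixels are conditionally independent of
   the label given (PT, HP), so *any* image-model performance is
   confounder-mediated by construction.
2. **Prepare** the scalar variables the way an imaging-informatics study
   would: feasibility filters (latencies outside [1 min, 1 day], BMI > 60
   blanked), staff-pool consolidation to the top 3 levels +
   `other_valid_entry`, train-median binarization, explicit `"(Missing)"`
   levels and regression imputation of BMI.
3. **Featurize** images with a deterministic filter bank (grid-pooled
   means / dispersions / oriented gradient energies — a stand-in for a
   pretrained CNN embedding, with an adapter for a real one) and reduce to
   10 principal components fit on the training partition.
4. **Model**: ridge-regularized logistic classifiers selected by
   cross-validated AUC over combinatorial predictor sets (IMG, PT, HP and
   unions), least-squares regressors for continuous targets, and a kernel
   Naive Bayes ensemble that mimics a clinician combining an image score
   with chart data under an (incorrect) independence assumption.
5. **Match**: rebuild the test set as 1:1 case–control cohorts at four
   depths — random, demographics (age + sex), all PT, PT + HP — by greedy
   Gower-dissimilarity matching without replacement. Matching removes
   covariate–fracture associations from the evaluation set, so whatever
   AUC survives is direct image signal.
6. **Measure**: ROC/AUC with DeLong variance and paired/unpaired
   comparison tests, Youden operating points, stratified bootstrap CIs,
   and per-covariate Fisher exact association tables.

The statistic at the core is the Mann–Whitney form of the AUC with
DeLong's structural-component variance: for cases `X_i` and controls
`Y_j`, placements `V10_i = mean_j [X_i > Y_j] + ½[X_i = Y_j]` and `V01_j`
symmetrically, `AUC = mean(V10)`, `var = var(V10)/m + var(V01)/n`, and
paired comparisons reuse the component covariances.

## Worked example

```r
library(confaudit)

cohort <- simulate_cohort(sim_config(seed = 1))   # ~10,500 radiographs
prep   <- prepare_cohort(cohort)
pcs    <- pca_reduce(featurize(render_images(cohort)), 10,
                     train = cohort$partition == "train")

tab <- cbind(prep$imputed, as.data.frame(pcs$scores))
tr  <- tab[cohort$partition == "train", ]
te  <- tab[cohort$partition == "test", ]

img <- fit_classifier(tr, "fracture", paste0("PC", 1:10), seed = 1)
roc(predict(img, te), te$fracture)
#> AUC 0.788 (95% CI 0.734-0.842; DeLong), 78 cases / 2492 controls

m <- match_controls(tab, level = "pt_hp", seed = 1)
sub <- te[match(c(m$pairs$case_id, m$pairs$control_id), te$image_id), ]
roc(predict(img, sub), sub$fracture)
#> AUC 0.540 (95% CI 0.449-0.631; DeLong), 78 cases / 78 controls
```

The first number says the image-only model "detects fracture" on a
conventional test set. The second says that once the test controls are
matched to the cases on every patient and process covariate, the same
model is statistically indistinguishable from a coin flip — its apparent
skill was routed through the confounders. Re-running with
`sim_config(seed = 1, beta_direct = 1.5)` (a strong true fracture line)
gives AUC ≈ 1.0 on *both* cohorts: a model with real signal is robust to
matching.

The numbered scripts under `analysis/` run the full study
(`01_simulate.R` … `06_evaluate.R`, writing tables under `results/`):
the per-target screen (every one of the 20 scalar variables is
image-predictable above chance; scanner model at AUC 1.00), the
predictor-set comparison (IMG 0.79 / PT 0.81 / HP 0.87 / IMG+PT+HP 0.92),
the cohort-characteristics table, the monotone drop in Fisher-significant
covariates across matching depths (12 → 12 → 8 → 6 → 2), and the CAD
scenario (PT 0.81 < NB(IMG, PT) 0.85 < multimodal IMG+PT 0.87, paired
DeLong p = 0.04/0.05).

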