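#!/usr/bin/env Rscript
# Scalar-variable preparation: feasibility filtering, staff-pool
# consolidation, train-median binarization and imputation. Writes the
# binarization dictionary and the cross-sectional covariate-fracture
# association screen (every covariate Fisher-tested against fracture).

library(confaudit)

cohort <- read_cohort("results/cohort")
prep <- prepare_cohort(cohort)

dir.create("results/prep", showWarnings = FALSE, recursive = TRUE)
binarization_dictionary(prep$binarized, "results/prep/dictionary.json")
write.csv(prep$binarized, "results/prep/binarized.csv", row.names = FALSE)
write.csv(prep$imputed, "results/prep/imputed.csv", row.names = FALSE)

at <- association_table(prep$binarized[cohort$partition == "test", ])
write.csv(at, "results/prep/associations_cs_test.csv", row.names = FALSE)
cat(sprintf("%d of %d covariates are Fisher-associated with fracture (p < 0.05)\n",
            attr(at, "n_significant"), nrow(at)))
print(at[order(at$p), c("covariate", "odds_ratio", "p")][1:8, ],
      row.names = FALSE)
if (!is.null(prep$bmi_model))
  cat(sprintf("BMI imputed by regression on %d predictors (fallback median %.1f)\n",
              length(prep$bmi_model$predictors), prep$bmi_model$fallback))
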