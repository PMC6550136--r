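#!/usr/bin/env Rscript
# Simulate the default observational hip-radiograph cohort.
#
# Patient traits drive fracture risk; fracture status drives triage
# (department, scanner, priority, timing), so acquisition metadata is
# confounded with the label by construction. Writes the cohort CSV (plus
# the generating config) under results/cohort/ and prints the headline
# characteristics.

library(confaudit)

seed <- 1
cohort <- simulate_cohort(sim_config(seed = seed))
write_cohort(cohort, "results/cohort")

cat(sprintf("cohort: %d radiographs from %d patients\n",
            nrow(cohort), length(unique(cohort$patient_id))))
cat(sprintf("fracture prevalence: %.2f%%\n", 100 * mean(cohort$fracture)))
print(cohort_summary(list(
  cs_train = cohort[cohort$partition == "train", ],
  cs_test  = cohort[cohort$partition == "test", ])))

# a handful of rendered examples for visual inspection
imgs <- render_images(cohort[1:8, ], attr(cohort, "config"))
write_cohort(cohort[1:8, ], "results/cohort_examples", images = imgs)
cat("wrote results/cohort/ and 8 example PNGs under results/cohort_examples/\n")
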