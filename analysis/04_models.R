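#!/usr/bin/env Rscript
# Supervised screens. First: can the image features predict each of the 20
# scalar variables (fracture + 5 PT + 14 HP)? Second: how does fracture
# prediction change across combinatorial predictor sets (IMG, PT, HP and
# their unions)?

library(confaudit)

cohort <- read_cohort("results/cohort")
prep <- prepare_cohort(cohort)
pcs <- as.matrix(read.csv("results/imaging/pc_scores.csv",
                          row.names = 1, check.names = FALSE))

dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

scr <- run_target_screen(cohort, prep = prep, pcs = pcs, seed = 1)
write.csv(scr$binary, "results/models/screen_binary.csv", row.names = FALSE)
write.csv(scr$continuous, "results/models/screen_continuous.csv",
          row.names = FALSE)
cat(sprintf("%d of %d binary targets predicted above chance (CI > 0.5)\n",
            sum(scr$binary$ci_lo > 0.5), nrow(scr$binary)))
cat("top image-predictable targets:\n")
print(head(scr$binary[order(-scr$binary$auc), ], 5), row.names = FALSE)
cat("continuous targets (held-out R^2):\n")
print(scr$continuous[order(-scr$continuous$r2), ], row.names = FALSE)

tab <- cbind(prep$imputed,
             as.data.frame(pcs)[match(cohort$image_id, rownames(pcs)), ])
tr <- tab[cohort$partition == "train", ]
te <- tab[cohort$partition == "test", ]
sets <- list("IMG", "PT", "HP", c("IMG", "PT"), c("PT", "HP"),
             c("IMG", "PT", "HP"))
rows <- lapply(sets, function(ps) {
  m <- fit_classifier(tr, "fracture", predictor_set(ps), seed = 1)
  r <- roc(predict(m, te), te$fracture)
  data.frame(predictors = paste(ps, collapse = "+"), auc = r$auc,
             ci_lo = r$ci[1], ci_hi = r$ci[2])
})
ps_auc <- do.call(rbind, rows)
write.csv(ps_auc, "results/models/predictor_sets.csv", row.names = FALSE)
cat("fracture AUC by predictor set:\n")
print(ps_auc, row.names = FALSE)
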