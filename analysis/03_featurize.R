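#!/usr/bin/env Rscript
# Render every radiograph, extract filter-bank features, reduce to 10
# principal components (fit on the training partition only), and ask
# which covariate best explains each component -- the unsupervised
# "what dominates pixel variation" screen.

library(confaudit)

cohort <- read_cohort("results/cohort")
cfg <- attr(cohort, "config")

imgs <- render_images(cohort, cfg)
feats <- featurize(imgs)
pca <- pca_reduce(feats, k = 10, train = cohort$partition == "train")

dir.create("results/imaging", showWarnings = FALSE, recursive = TRUE)
write.csv(data.frame(image_id = rownames(pca$scores), pca$scores),
          "results/imaging/pc_scores.csv", row.names = FALSE)
write.csv(data.frame(pc = paste0("PC", 1:10), explained = pca$explained),
          "results/imaging/pca_explained.csv", row.names = FALSE)
cat(sprintf("10 PCs explain %.0f%% of feature variance\n",
            100 * sum(pca$explained)))

r2 <- pc_covariate_r2(pca$scores,
                      cohort[, c("scanner_model", "scanner_manufacturer",
                                 "department", "view", "age", "sex", "bmi",
                                 "priority", "year")])
write.csv(r2, "results/imaging/pc_covariate_r2.csv", row.names = FALSE)
best <- do.call(rbind, lapply(split(r2, r2$pc), head, 1))
cat("best predictor of each component:\n")
print(best, row.names = FALSE)
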