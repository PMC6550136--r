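#!/usr/bin/env Rscript
# The headline audit. (1) Evaluate the image-only fracture classifier on
# the cross-sectional test set and on each matched cohort: with no direct
# fracture signature in the pixels (beta_direct = 0, the default) its AUC
# should collapse toward 0.5 once PT + HP associations are matched away.
# (2) The CAD scenario: a Naive Bayes ensemble of the image score with
# patient data should beat patient data alone but lose to a multimodal
# model that sees the interdependencies.

library(confaudit)

cohort <- read_cohort("results/cohort")
prep <- prepare_cohort(cohort)
pcs <- as.matrix(read.csv("results/imaging/pc_scores.csv",
                          row.names = 1, check.names = FALSE))

tab <- cbind(prep$imputed,
             as.data.frame(pcs)[match(cohort$image_id, rownames(pcs)), ])
tr <- tab[cohort$partition == "train", ]
te <- tab[cohort$partition == "test", ]
roles <- cohort_roles()

img <- fit_classifier(tr, "fracture", colnames(pcs), seed = 1)

dir.create("results/evaluate", showWarnings = FALSE, recursive = TRUE)
rows <- list()
rocs <- list(cs_test = roc(predict(img, te), te$fracture))
for (lv in c("random", "demographics", "pt", "pt_hp")) {
  pairs <- read.csv(sprintf("results/matching/pairs_%s.csv", lv),
                    colClasses = "character")
  sub <- te[match(c(pairs$case_id, pairs$control_id), te$image_id), ]
  rocs[[lv]] <- roc(predict(img, sub), sub$fracture)
}
collapse <- data.frame(
  cohort = names(rocs),
  auc = vapply(rocs, function(r) r$auc, 0),
  ci_lo = vapply(rocs, function(r) r$ci[1], 0),
  ci_hi = vapply(rocs, function(r) r$ci[2], 0),
  p_vs_cs = c(NA, vapply(rocs[-1], function(r)
    delong_test(rocs$cs_test, r, paired = FALSE)$p, 0)))
write.csv(collapse, "results/evaluate/collapse.csv", row.names = FALSE)
cat("image-only AUC by test cohort:\n")
print(collapse, row.names = FALSE)

## CAD scenario: secondary NB integration vs direct multimodal models
img_te <- setNames(predict(img, te), te$image_id)
nb_pt <- fit_nb_ensemble(tr, oof_scores(img), roles$pt)
nb_pthp <- fit_nb_ensemble(tr, oof_scores(img),
                           c(roles$pt, roles$hp_at_acquisition))
mdl <- function(preds) fit_classifier(tr, "fracture", preds, seed = 1)
r <- function(m) roc(predict(m, te), te$fracture)
r_nb <- function(m) roc(predict(m, te, image_scores = img_te), te$fracture)
arms <- list(
  PT = r(mdl(predictor_set("PT"))),
  `NB(IMG,PT)` = r_nb(nb_pt),
  `IMG+PT` = r(mdl(predictor_set(c("IMG", "PT")))),
  `PT+HP` = r(mdl(predictor_set(c("PT", "HP")))),
  `NB(IMG,PT+HP)` = r_nb(nb_pthp),
  `IMG+PT+HP` = r(mdl(predictor_set(c("IMG", "PT", "HP")))))
cad <- data.frame(model = names(arms),
                  auc = vapply(arms, function(x) x$auc, 0),
                  ci_lo = vapply(arms, function(x) x$ci[1], 0),
                  ci_hi = vapply(arms, function(x) x$ci[2], 0))
write.csv(cad, "results/evaluate/cad_ensembles.csv", row.names = FALSE)
cat("\nCAD-scenario comparison:\n")
print(cad, row.names = FALSE)
cat(sprintf("paired DeLong NB(IMG,PT) vs PT: p = %.2g; vs IMG+PT: p = %.2g\n",
            delong_test(arms$`NB(IMG,PT)`, arms$PT, paired = TRUE)$p,
            delong_test(arms$`NB(IMG,PT)`, arms$`IMG+PT`, paired = TRUE)$p))
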