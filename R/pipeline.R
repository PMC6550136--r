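# End-to-end experiment orchestration: simulate -> prep -> featurize ->
# fit -> match -> evaluate -> report.

#' Experiment configuration
#'
#' @param sim a [sim_config()].
#' @param predictor_sets list of character vectors over
#'   `c("IMG", "PT", "HP")` to fit for fracture.
#' @param match_levels matching depths to evaluate.
#' @param pca_k number of image principal components.
#' @param cv_folds CV folds for classifier selection and NB image scores.
#' @param boot_B bootstrap resamples for reported CIs (0 disables).
#' @param alpha significance level for association screens.
#' @param seed global experiment seed (flows into folds, matching and
#'   bootstrap; the cohort uses `sim$seed`).
#' @param with_nb fit the Naive Bayes ensembles and multimodal
#'   comparisons (the CAD-scenario arm).
#' @param with_screen run the per-target screen (every covariate predicted
#'   from the image features).
#' @param out_dir optional directory; when set, [run_experiment()] writes
#'   the report tables there.
#' @return validated list of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              predictor_sets = list("IMG", "PT", "HP",
                                                    c("IMG", "PT"),
                                                    c("PT", "HP"),
                                                    c("IMG", "PT", "HP")),
                              match_levels = c("random", "demographics",
                                               "pt", "pt_hp"),
                              pca_k = 10, cv_folds = 10, boot_B = 0,
                              alpha = 0.05, seed = 1,
                              with_nb = TRUE, with_screen = FALSE,
                              out_dir = NULL) {
  cfg <- list(sim = validate_sim_config(unclass(sim)),
              predictor_sets = predictor_sets,
              match_levels = match.arg(match_levels,
                                       c("random", "demographics", "pt",
                                         "pt_hp"), several.ok = TRUE),
              pca_k = pca_k, cv_folds = cv_folds, boot_B = boot_B,
              alpha = alpha, seed = seed, with_nb = isTRUE(with_nb),
              with_screen = isTRUE(with_screen), out_dir = out_dir)
  if (!is.numeric(cfg$pca_k) || cfg$pca_k < 1)
    ca_stop("invalid experiment_config field 'pca_k'")
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' Unknown keys are rejected so silent typos cannot change an experiment.
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    ca_stop("unknown experiment_config key(s): %s",
            paste(unknown, collapse = ", "))
  if (!is.null(raw$sim)) {
    sim_known <- names(formals(sim_config))
    sim_unknown <- setdiff(names(raw$sim), sim_known)
    if (length(sim_unknown))
      ca_stop("unknown sim_config key(s): %s",
              paste(sim_unknown, collapse = ", "))
    defaults <- sim_config()
    for (k in names(raw$sim)) {
      v <- raw$sim[[k]]
      if (!is.null(names(defaults[[k]]))) v <- unlist(v)
      defaults[[k]] <- v
    }
    raw$sim <- validate_sim_config(unclass(defaults))
  }
  do.call(experiment_config, raw)
}

#' @rdname read_experiment_config
#' @param config an `experiment_config` to serialize.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- lapply(unclass(x$sim), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

# featurize + reduce a cohort's images; train-fit PCA
ca_image_pcs <- function(cohort, config, pca_k) {
  imgs <- render_images(cohort, config)
  feats <- featurize(imgs)
  pca <- pca_reduce(feats, k = pca_k, train = cohort$partition == "train")
  list(pcs = pca$scores, pca = pca, features = feats)
}

#' Run the full confounding-audit experiment
#'
#' Simulates (or accepts) a cohort, prepares the scalar variables,
#' renders and featurizes the images, fits fracture classifiers for each
#' predictor set, builds the matched case-control test cohorts, and
#' evaluates the image-only classifier on every test set, with DeLong
#' comparisons against the cross-sectional test set. With `with_nb` it
#' also fits the Naive Bayes ensembles (image score + covariates) and
#' their multimodal counterparts and runs the paired comparisons.
#'
#' @param config an [experiment_config()].
#' @param cohort optional pre-generated `cohort_table` (defaults to
#'   `simulate_cohort(config$sim)`).
#' @return list of class `experiment_report`; see the elements
#'   `cohorts` (Table-1-style summary), `associations` (per-cohort
#'   significant-covariate counts), `auc_by_cohort` (the image-only
#'   collapse table), `predictor_sets`, `nb`, and `screen`.
#' @export
run_experiment <- function(config = experiment_config(), cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- cohort %||% simulate_cohort(config$sim)
  prep <- prepare_cohort(cohort)
  train <- cohort$partition == "train"

  im <- ca_image_pcs(cohort, attr(cohort, "config") %||% config$sim,
                     config$pca_k)
  pcs <- as.data.frame(im$pcs)
  pc_names <- colnames(im$pcs)

  # modelling tables: imputed scalars + PC scores
  tab <- cbind(prep$imputed, pcs[match(cohort$image_id,
                                       rownames(im$pcs)), , drop = FALSE])
  tr_tab <- tab[train, , drop = FALSE]
  te_tab <- tab[!train, , drop = FALSE]

  ## fracture models over predictor sets
  models <- list()
  for (ps in config$predictor_sets) {
    nm <- paste(ps, collapse = "+")
    preds <- predictor_set(ps, pc_names = pc_names)
    models[[nm]] <- fit_classifier(tr_tab, "fracture", preds,
                                   cv_folds = config$cv_folds,
                                   seed = config$seed)
  }

  ## matched cohorts on the imputed test partition
  matched <- list()
  for (lv in config$match_levels)
    matched[[lv]] <- match_controls(tab, level = lv, seed = config$seed)

  ## image-only collapse table
  img_model <- models[["IMG"]]
  eval_sets <- c(list(cs_test = te_tab),
                 lapply(matched, function(m)
                   te_tab[match(c(m$pairs$case_id, m$pairs$control_id),
                                te_tab$image_id), , drop = FALSE]))
  rocs <- lapply(eval_sets, function(d)
    roc(predict(img_model, d), d$fracture))
  auc_by_cohort <- data.frame(
    cohort = names(rocs),
    n = vapply(eval_sets, nrow, 0L),
    auc = vapply(rocs, function(r) r$auc, 0),
    ci_lo = vapply(rocs, function(r) r$ci[1], 0),
    ci_hi = vapply(rocs, function(r) r$ci[2], 0),
    stringsAsFactors = FALSE)
  auc_by_cohort$p_vs_cs <- c(NA, vapply(rocs[-1], function(r)
    delong_test(rocs$cs_test, r, paired = FALSE)$p, 0))
  if (config$boot_B > 0) {
    bci <- t(vapply(eval_sets, function(d)
      bootstrap_ci(predict(img_model, d), d$fracture, B = config$boot_B,
                   seed = config$seed), numeric(2)))
    auc_by_cohort$boot_lo <- bci[, 1]; auc_by_cohort$boot_hi <- bci[, 2]
  }

  ## predictor-set comparison on the cross-sectional test set
  ps_rocs <- lapply(models, function(mdl)
    roc(predict(mdl, te_tab), te_tab$fracture))
  predictor_auc <- data.frame(
    predictors = names(ps_rocs),
    auc = vapply(ps_rocs, function(r) r$auc, 0),
    ci_lo = vapply(ps_rocs, function(r) r$ci[1], 0),
    ci_hi = vapply(ps_rocs, function(r) r$ci[2], 0),
    stringsAsFactors = FALSE)

  ## Naive Bayes CAD-scenario arm
  nb <- NULL
  if (config$with_nb && all(c("IMG", "PT", "IMG+PT") %in% names(models))) {
    img_oof <- oof_scores(img_model)
    img_test <- setNames(predict(img_model, te_tab), te_tab$image_id)
    nb_fit <- function(cov_cols) {
      m <- fit_nb_ensemble(tr_tab, img_oof, cov_cols)
      roc(predict(m, te_tab, image_scores = img_test), te_tab$fracture)
    }
    roles <- cohort_roles()
    nb_pt <- nb_fit(roles$pt)
    comp <- function(a, b) delong_test(a, b, paired = TRUE)$p
    nb <- list(
      nb_img_pt = nb_pt,
      ordering = data.frame(
        model = c("PT", "NB(IMG,PT)", "IMG+PT"),
        auc = c(ps_rocs$PT$auc, nb_pt$auc, ps_rocs$`IMG+PT`$auc)),
      p_nb_vs_pt = comp(nb_pt, ps_rocs$PT),
      p_nb_vs_multimodal = comp(nb_pt, ps_rocs$`IMG+PT`))
    if (all(c("PT+HP", "IMG+PT+HP") %in% names(models))) {
      nb_pthp <- nb_fit(c(roles$pt, roles$hp_at_acquisition))
      nb$nb_img_pthp <- nb_pthp
      nb$ordering <- rbind(nb$ordering, data.frame(
        model = c("PT+HP", "NB(IMG,PT+HP)", "IMG+PT+HP"),
        auc = c(ps_rocs$`PT+HP`$auc, nb_pthp$auc,
                ps_rocs$`IMG+PT+HP`$auc)))
    }
  }

  ## association screens per cohort (binarized covariates)
  assoc <- list(cs_test = association_table(
    prep$binarized[!train, , drop = FALSE], alpha = config$alpha))
  for (lv in names(matched))
    assoc[[lv]] <- association_table(
      prep$binarized, ids = c(matched[[lv]]$pairs$case_id,
                              matched[[lv]]$pairs$control_id),
      alpha = config$alpha)
  n_signif <- vapply(assoc, function(a) attr(a, "n_significant"), 0L)

  ## Table-1-style cohort characteristics
  cohorts <- cohort_summary(c(
    list(cs_train = cohort[train, , drop = FALSE],
         cs_test = cohort[!train, , drop = FALSE]),
    matched))

  screen <- if (config$with_screen)
    run_target_screen(cohort, prep = prep, pcs = im$pcs,
                      cv_folds = config$cv_folds, seed = config$seed)

  report <- structure(
    list(config = config, cohorts = cohorts,
         auc_by_cohort = auc_by_cohort, rocs = rocs,
         predictor_auc = predictor_auc, nb = nb,
         associations = assoc, n_significant = n_signif,
         matched = matched, models = models, screen = screen,
         pca_explained = im$pca$explained),
    class = "experiment_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Per-target screen: predict every covariate from the image features
#'
#' Fits one image-only (PC-score) classifier per binarized target --
#' fracture plus all 19 covariates -- and one regressor per continuous
#' covariate, reporting AUC with DeLong CI (binary) or held-out
#' R-squared (continuous) on the test partition. Targets with a single
#' class are skipped with a warning.
#'
#' @param cohort a `cohort_table`.
#' @param prep optional [prepare_cohort()] output (recomputed otherwise).
#' @param pcs optional PC score matrix (recomputed otherwise).
#' @param cv_folds,seed passed to [fit_classifier()].
#' @return list with `binary` (target, auc, ci) and `continuous`
#'   (target, r2) data.frames.
#' @export
run_target_screen <- function(cohort, prep = NULL, pcs = NULL,
                              cv_folds = 10, seed = 1) {
  prep <- prep %||% prepare_cohort(cohort)
  if (is.null(pcs)) {
    cfg <- attr(cohort, "config")
    if (is.null(cfg)) ca_stop("cohort has no config; pass pcs")
    pcs <- ca_image_pcs(cohort, cfg, 10)$pcs
  }
  pc_names <- colnames(pcs)
  train <- cohort$partition == "train"

  bint <- cbind(prep$binarized,
                as.data.frame(pcs)[match(cohort$image_id, rownames(pcs)), ,
                                   drop = FALSE])
  binary <- list()
  targets <- setdiff(names(prep$binarized),
                     c("image_id", "patient_id", "partition"))
  for (tg in targets) {
    dtr <- bint[train, , drop = FALSE]
    dte <- bint[!train, , drop = FALSE]
    dtr <- dtr[!is.na(dtr[[tg]]), ]; dte <- dte[!is.na(dte[[tg]]), ]
    if (length(unique(dtr[[tg]])) < 2 || length(unique(dte[[tg]])) < 2) {
      warning(sprintf("screen target '%s' has a single class; skipped", tg))
      next
    }
    mdl <- fit_classifier(dtr, tg, pc_names, cv_folds = cv_folds,
                          seed = seed)
    r <- roc(predict(mdl, dte), dte[[tg]])
    binary[[tg]] <- data.frame(target = tg, auc = r$auc,
                               ci_lo = r$ci[1], ci_hi = r$ci[2],
                               stringsAsFactors = FALSE)
  }

  cont <- list()
  imp <- cbind(prep$imputed,
               as.data.frame(pcs)[match(cohort$image_id, rownames(pcs)), ,
                                  drop = FALSE])
  for (tg in intersect(cohort_roles()$continuous, names(imp))) {
    mdl <- fit_regressor(imp[train, , drop = FALSE], tg, pc_names)
    cont[[tg]] <- data.frame(target = tg,
                             r2 = regressor_r2(mdl, imp[!train, ,
                                                        drop = FALSE]),
                             stringsAsFactors = FALSE)
  }
  list(binary = do.call(rbind, binary), continuous = do.call(rbind, cont))
}

#' Write an experiment report to disk
#'
#' CSV tables (cohort summary, AUC-by-cohort, predictor-set AUCs,
#' association tables, matched pair lists, ROC curves) plus a JSON
#' overview, so every reported number is traceable to a persisted file.
#'
#' @param report an `experiment_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE)
  utils::write.csv(report$cohorts, file.path(dir, "cohort_summary.csv"))
  w(report$auc_by_cohort, "auc_by_cohort.csv")
  w(report$predictor_auc, "predictor_sets.csv")
  for (nm in names(report$associations))
    w(report$associations[[nm]], sprintf("associations_%s.csv", nm))
  for (nm in names(report$matched))
    w(report$matched[[nm]]$pairs, sprintf("pairs_%s.csv", nm))
  for (nm in names(report$rocs))
    w(report$rocs[[nm]]$curve, sprintf("roc_%s.csv", nm))
  if (!is.null(report$screen)) {
    w(report$screen$binary, "screen_binary.csv")
    w(report$screen$continuous, "screen_continuous.csv")
  }
  overview <- list(
    n_significant = as.list(report$n_significant),
    auc_by_cohort = report$auc_by_cohort,
    predictor_auc = report$predictor_auc,
    pca_explained = report$pca_explained,
    nb_ordering = if (!is.null(report$nb)) report$nb$ordering)
  jsonlite::write_json(overview, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report\n")
  cat("image-only AUC by test cohort:\n")
  print(x$auc_by_cohort, row.names = FALSE)
  cat("significant covariate-fracture associations per cohort:\n")
  print(x$n_significant)
  if (!is.null(x$nb)) {
    cat("CAD-scenario ordering:\n")
    print(x$nb$ordering, row.names = FALSE)
  }
  invisible(x)
}
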