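# Classifiers and regressors over combinatorial predictor sets.
#
# Binary targets: logistic regression with a small L2 (ridge) grid, the
# penalty chosen by cross-validated AUC; the grid's zero point is plain
# maximum likelihood (refit with stats::glm when selected). Continuous
# targets: least squares. Predictor sets expand IMG to the 10 PC scores
# and PT/HP to their (binarized or imputed) scalar columns.

#' Expand a predictor set to design-matrix columns
#'
#' @param sets character subset of `c("IMG", "PT", "HP")`.
#' @param pc_names names of the PC score columns (for IMG).
#' @param roles variable roles, see [cohort_roles()].
#' @param hp_at_acquisition restrict HP to acquisition-time covariates
#'   (default TRUE: explanatory models only use what is known when the
#'   image is taken).
#' @return character vector of column names.
#' @export
predictor_set <- function(sets, pc_names = paste0("PC", 1:10),
                          roles = cohort_roles(),
                          hp_at_acquisition = TRUE) {
  sets <- match.arg(sets, c("IMG", "PT", "HP"), several.ok = TRUE)
  out <- character()
  if ("IMG" %in% sets) out <- c(out, pc_names)
  if ("PT" %in% sets) out <- c(out, roles$pt)
  if ("HP" %in% sets)
    out <- c(out, if (hp_at_acquisition) roles$hp_at_acquisition
             else setdiff(roles$hp, "order_datetime"))
  unique(out)
}

# design matrix with recorded factor levels so train/test expansion agrees
ca_design <- function(data, predictors, xlev = NULL) {
  missing <- setdiff(predictors, names(data))
  if (length(missing))
    ca_stop("missing predictor column(s): %s", paste(missing, collapse = ", "))
  d <- data[, predictors, drop = FALSE]
  for (v in predictors) if (!is.numeric(d[[v]])) {
    lv <- if (!is.null(xlev) && v %in% names(xlev)) xlev[[v]]
    else levels(factor(d[[v]]))
    d[[v]] <- factor(d[[v]], levels = lv)
  }
  xlev_out <- lapply(d[!vapply(d, is.numeric, TRUE)], levels)
  X <- model.matrix(~ . , data = d)
  list(X = X[, -1, drop = FALSE], xlev = xlev_out)
}

ca_cv_folds <- function(y, k, seed) {
  ca_with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    fold
  })
}

#' Fit a (ridge-regularized) logistic classifier
#'
#' Maximum-likelihood logistic regression over a small L2 grid; the
#' penalty is selected by `cv_folds`-fold cross-validated AUC on the
#' training rows (class-stratified folds). `lambda = 0` means plain MLE
#' and is refit with [stats::glm()] when selected. Rows with a missing
#' predictor or target are dropped.
#'
#' @param train_table training data.frame.
#' @param target name of the 0/1 target column.
#' @param predictors character vector of predictor columns (see
#'   [predictor_set()]); matrix columns (e.g. PC scores) must already be
#'   joined onto the table.
#' @param cv_folds number of CV folds (default 10).
#' @param lambda_grid L2 penalties to consider.
#' @param seed fold-assignment seed.
#' @return object of class `ca_classifier` with coefficients, the CV-AUC
#'   table, the selected lambda, and out-of-fold training scores
#'   (accessible via [oof_scores()]), used unbiasedly by the Naive Bayes
#'   ensemble.
#' @export
fit_classifier <- function(train_table, target, predictors,
                           cv_folds = 10,
                           lambda_grid = c(0, 1e-3, 1e-2, 1e-1, 1),
                           seed = 1) {
  ca_check_cols(train_table, target, "train_table")
  des <- ca_design(train_table, predictors)
  y <- as.integer(train_table[[target]])
  ok <- complete.cases(des$X) & !is.na(y)
  X <- des$X[ok, , drop = FALSE]; y <- y[ok]
  if (length(unique(y)) < 2)
    ca_stop("target '%s' has a single class", target)
  n <- length(y)
  folds <- ca_cv_folds(y, cv_folds, seed)

  fit_one <- function(Xtr, ytr, lambda) {
    p <- ncol(Xtr)
    if (p == 1) Xtr <- cbind(Xtr, 0)   # glmnet needs >= 2 columns
    # lambda 0 is approximated by a tiny ridge here; the selected model is
    # refit exactly (glm) below
    g <- suppressWarnings(
      glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                     lambda = max(lambda, 1e-6), standardize = TRUE))
    list(a0 = as.numeric(g$a0), beta = as.numeric(g$beta)[seq_len(p)])
  }
  score <- function(f, Xn) plogis(drop(Xn %*% f$beta) + f$a0)

  cv <- matrix(NA_real_, length(lambda_grid), 1,
               dimnames = list(paste0("lambda_", lambda_grid), "cv_auc"))
  oof <- matrix(NA_real_, n, length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2 || min(table(y[tr])) < 2) next
      f <- fit_one(X[tr, , drop = FALSE], y[tr], lambda_grid[li])
      oof[!tr, li] <- score(f, X[!tr, , drop = FALSE])
    }
    if (length(unique(y[!is.na(oof[, li])])) == 2)
      cv[li, 1] <- ca_placements(oof[!is.na(oof[, li]), li],
                                 y[!is.na(oof[, li])])$auc
  }
  if (all(is.na(cv[, 1]))) {
    best <- 1L   # degenerate CV (tiny folds); fall back to the grid head
  } else best <- which.max(cv[, 1])
  lambda <- lambda_grid[best]

  if (lambda == 0) {
    full <- suppressWarnings(
      glm.fit(cbind(1, X), y, family = binomial()))
    coefs <- unname(full$coefficients)
    final <- list(a0 = coefs[1], beta = coefs[-1])
    if (anyNA(final$beta)) {  # collinear columns: fall back to ridge floor
      final <- fit_one(X, y, 0)
    }
  } else final <- fit_one(X, y, lambda)

  structure(list(target = target, predictors = predictors,
                 family = "logistic",
                 a0 = final$a0, beta = setNames(final$beta, colnames(X)),
                 lambda = lambda, cv_auc = cv, xlev = des$xlev,
                 oof = setNames(oof[, best], train_table$image_id[ok]),
                 seed = seed, n = n),
            class = "ca_classifier")
}

#' Out-of-fold training scores of a fitted classifier
#' @param model a `ca_classifier`.
#' @return named numeric vector (names = `image_id` when available).
#' @export
oof_scores <- function(model) model$oof

#' @export
predict.ca_classifier <- function(object, newdata, ...) {
  des <- ca_design(newdata, object$predictors, xlev = object$xlev)
  X <- des$X[, names(object$beta), drop = FALSE]
  unname(plogis(drop(X %*% object$beta) + object$a0))
}

#' Persist / restore a fitted classifier as JSON
#'
#' @param model a `ca_classifier`.
#' @param path JSON file.
#' @return `path` invisibly; `read_classifier()` returns a scoring-capable
#'   `ca_classifier` (without CV artifacts).
#' @export
write_classifier <- function(model, path) {
  jsonlite::write_json(
    list(target = model$target, predictors = model$predictors,
         family = model$family, a0 = model$a0,
         beta = as.list(model$beta), lambda = model$lambda,
         xlev = model$xlev),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(target = x$target, predictors = x$predictors,
                 family = x$family, a0 = x$a0, beta = unlist(x$beta),
                 lambda = x$lambda,
                 xlev = lapply(x$xlev, as.character)),
            class = "ca_classifier")
}

#' Fit a least-squares regressor for a continuous target
#'
#' Ordinary least squares; a rank-deficient design falls back to the
#' minimum-norm solution (Moore-Penrose) with a warning.
#'
#' @inheritParams fit_classifier
#' @return object of class `ca_regressor`.
#' @export
fit_regressor <- function(train_table, target, predictors) {
  ca_check_cols(train_table, target, "train_table")
  des <- ca_design(train_table, predictors)
  y <- as.numeric(train_table[[target]])
  ok <- complete.cases(des$X) & !is.na(y)
  X <- cbind(`(Intercept)` = 1, des$X[ok, , drop = FALSE])
  y <- y[ok]
  q <- qr(X)
  if (q$rank < ncol(X)) {
    warning("rank-deficient design; using the minimum-norm solution")
    coefs <- drop(MASS::ginv(X) %*% y)
  } else coefs <- qr.coef(q, y)
  names(coefs) <- colnames(X)
  structure(list(target = target, predictors = predictors,
                 family = "linear", coefficients = coefs,
                 xlev = des$xlev, n = length(y)),
            class = "ca_regressor")
}

#' @export
predict.ca_regressor <- function(object, newdata, ...) {
  des <- ca_design(newdata, object$predictors, xlev = object$xlev)
  X <- cbind(1, des$X[, names(object$coefficients)[-1], drop = FALSE])
  unname(drop(X %*% object$coefficients))
}

#' Held-out R-squared of a regressor
#' @param model a `ca_regressor`.
#' @param table evaluation data.frame containing the target.
#' @return coefficient of determination of predicted vs actual.
#' @export
regressor_r2 <- function(model, table) {
  pred <- predict(model, table)
  y <- as.numeric(table[[model$target]])
  ok <- !is.na(pred) & !is.na(y)
  1 - sum((y[ok] - pred[ok])^2) / sum((y[ok] - mean(y[ok]))^2)
}
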