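# Kernel Naive Bayes evidence ensemble.
#
# Models how a clinician might combine an image model's risk score with
# chart data while (wrongly, when confounded) assuming the evidence
# sources are independent. Continuous predictors -- including the image
# score -- get class-conditional Gaussian kernel densities (Silverman
# bandwidth per class); categoricals get Laplace-smoothed frequency
# tables; priors are training class frequencies; the posterior follows
# the product rule.

# probability scores enter the ensemble on the logit scale: kernel
# densities behave badly on a bounded, highly skewed [0,1] score, and the
# logit makes the class-conditional score distributions near-Gaussian
ca_logit_clamp <- function(p) qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))

ca_silverman_bw <- function(x) {
  n <- length(x)
  s <- min(sd(x), stats::IQR(x) / 1.34)
  if (!is.finite(s) || s <= 0) s <- max(sd(x), 1e-3)
  if (!is.finite(s) || s <= 0) s <- 1e-3
  0.9 * s * n^(-1 / 5)
}

ca_kde_eval <- function(x, sample, bw) {
  # mean of Gaussian kernels; vectorized over x
  vapply(x, function(xi) mean(dnorm((xi - sample) / bw)) / bw, 0)
}

#' Fit the Naive Bayes ensemble of an image score and covariates
#'
#' @param train_table training data.frame (must contain the target and
#'   covariate columns).
#' @param image_scores named numeric vector of out-of-fold image-model
#'   scores on the training rows (names = `image_id`), e.g.
#'   `oof_scores(img_model)` from a 10-fold CV fit -- out-of-fold so the
#'   density of the image evidence is estimated without optimism. Scores
#'   are modelled on the logit scale internally (probabilities in, clamped
#'   to avoid infinities). `NULL` fits a covariates-only Naive Bayes.
#' @param covariates character vector of covariate columns.
#' @param target 0/1 target column (default `"fracture"`).
#' @param laplace Laplace smoothing count for categorical tables.
#' @return object of class `ca_nb`.
#' @export
fit_nb_ensemble <- function(train_table, image_scores, covariates,
                            target = "fracture", laplace = 1) {
  ca_check_cols(train_table, c(target, covariates), "train_table")
  tab <- train_table
  if (!is.null(image_scores)) {
    sc <- image_scores[match(tab$image_id, names(image_scores))]
    tab$.img_score <- ca_logit_clamp(as.numeric(sc))
    covariates <- c(".img_score", covariates)
  }
  y <- as.integer(tab[[target]])
  if (length(unique(y[!is.na(y)])) < 2) ca_stop("empty class in target")
  classes <- c(0L, 1L)
  priors <- vapply(classes, function(cl) mean(y == cl, na.rm = TRUE), 0)
  dens <- lapply(covariates, function(v) {
    x <- tab[[v]]
    if (is.numeric(x) && !ca_is_binary(x)) {
      per_class <- lapply(classes, function(cl) {
        xi <- x[y == cl & !is.na(x)]
        list(sample = xi, bw = ca_silverman_bw(xi))
      })
      list(type = "kde", per_class = per_class)
    } else {
      lv <- levels(factor(x))
      per_class <- lapply(classes, function(cl) {
        cnt <- table(factor(x[y == cl], levels = lv))
        (cnt + laplace) / sum(cnt + laplace)
      })
      list(type = "table", levels = lv, per_class = per_class)
    }
  })
  names(dens) <- covariates
  structure(list(target = target, covariates = covariates,
                 family = "naive-bayes-ensemble",
                 priors = priors, densities = dens,
                 uses_image = !is.null(image_scores)),
            class = "ca_nb")
}

#' @export
predict.ca_nb <- function(object, newdata, image_scores = NULL, ...) {
  tab <- newdata
  if (object$uses_image) {
    if (is.null(image_scores))
      ca_stop("this ensemble needs image_scores for newdata")
    tab$.img_score <- ca_logit_clamp(as.numeric(
      image_scores[match(tab$image_id, names(image_scores))]))
  }
  n <- nrow(tab)
  loglik <- matrix(log(object$priors), n, 2, byrow = TRUE)
  for (v in object$covariates) {
    if (!v %in% names(tab)) ca_stop("missing covariate column: %s", v)
    x <- tab[[v]]
    dv <- object$densities[[v]]
    for (ci in 1:2) {
      if (dv$type == "kde") {
        pc <- dv$per_class[[ci]]
        ll <- rep(0, n)
        obs <- !is.na(x)
        ll[obs] <- log(pmax(ca_kde_eval(x[obs], pc$sample, pc$bw), 1e-300))
      } else {
        p <- dv$per_class[[ci]]
        idx <- match(as.character(x), dv$levels)
        ll <- ifelse(is.na(idx), 0, log(as.numeric(p)[idx]))
        ll[is.na(ll)] <- 0
      }
      loglik[, ci] <- loglik[, ci] + ll
    }
  }
  1 / (1 + exp(loglik[, 1] - loglik[, 2]))
}
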