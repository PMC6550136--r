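# ROC / AUC machinery with DeLong variance and comparison tests.
#
# AUC is computed with midranks (ties get half credit), identical to the
# Mann-Whitney U statistic. Variance follows DeLong's structural
# components: per-case placements V10 and per-control placements V01, with
# var(AUC) = var(V10)/m + var(V01)/n. Paired comparisons reuse the
# component covariances; unpaired comparisons set the covariance to 0.

ca_placements <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  m <- length(cases); n <- length(controls)
  r_all <- rank(c(cases, controls), ties.method = "average")
  r_cases <- rank(cases, ties.method = "average")
  r_controls <- rank(controls, ties.method = "average")
  # midrank identity: placement of case i among controls
  v10 <- (r_all[seq_len(m)] - r_cases) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_controls) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC analysis with DeLong variance, Youden point and PR curve
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   disease-like).
#' @param labels 0/1 vector (1 = case); both classes must be present.
#' @param conf_level confidence level for the Wald CI (default 0.95).
#' @return object of class `ca_roc`: `auc`, `var` (DeLong), `ci`
#'   (truncated to [0, 1]), `curve` (data.frame fpr/tpr/threshold),
#'   `youden` (threshold, sensitivity, specificity), `pr` (recall /
#'   precision table), `average_precision`, counts `m` (cases) / `n`
#'   (controls), and the structural components for comparison tests.
#' @export
roc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2)
    ca_stop("roc() needs both cases and controls")
  pl <- ca_placements(scores, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  v <- var(pl$v10) / m + var(pl$v01) / n
  if (m == 1) v <- var(pl$v01) / n
  if (n == 1) v <- var(pl$v10) / m
  if (m == 1 && n == 1) v <- 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * sqrt(v), 0), 1)

  # ROC curve over unique thresholds (descending)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
  curve <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)

  # Youden: maximize sens + spec - 1; ties -> higher sensitivity
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.max(tpr[best])]
  youden <- list(threshold = thr[best], sensitivity = tpr[best],
                 specificity = 1 - fpr[best], j = j[best])

  # precision-recall + average precision (step integration)
  prec <- vapply(thr, function(t) {
    sel <- scores >= t
    if (!any(sel)) return(NA_real_)
    mean(labels[sel] == 1)
  }, 0)
  pr <- data.frame(threshold = thr, recall = tpr, precision = prec)
  dr <- diff(tpr)
  ap <- sum(dr * prec[-1], na.rm = TRUE)

  structure(list(auc = pl$auc, var = v, ci = ci, conf_level = conf_level,
                 curve = curve, youden = youden, pr = pr,
                 average_precision = ap, m = m, n = n,
                 v10 = pl$v10, v01 = pl$v01,
                 scores = scores, labels = labels),
            class = "ca_roc")
}

#' @export
print.ca_roc <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f; DeLong), %d cases / %d controls\n",
              x$auc, 100 * x$conf_level, x$ci[1], x$ci[2], x$m, x$n))
  cat(sprintf("Youden: thr %.3g, sens %.3f, spec %.3f | AP %.3f\n",
              x$youden$threshold, x$youden$sensitivity,
              x$youden$specificity, x$average_precision))
  invisible(x)
}

#' DeLong test comparing two AUCs
#'
#' Paired: both ROC curves must be computed on the same records (identical
#' label vectors); the covariance of the structural components enters the
#' variance of the difference. Unpaired: cohorts are independent and the
#' covariance is 0.
#'
#' @param roc_a,roc_b `ca_roc` objects.
#' @param paired logical.
#' @return object of class `ca_roc_test`: `auc_a`, `auc_b`, `difference`,
#'   `z`, `p` (two-sided normal), `paired`.
#' @export
delong_test <- function(roc_a, roc_b, paired = FALSE) {
  if (paired) {
    if (roc_a$m != roc_b$m || roc_a$n != roc_b$n ||
        !isTRUE(all.equal(roc_a$labels, roc_b$labels)))
      ca_stop("paired comparison requires identical record sets")
    cv <- cov(roc_a$v10, roc_b$v10) / roc_a$m +
      cov(roc_a$v01, roc_b$v01) / roc_a$n
  } else cv <- 0
  d <- roc_a$auc - roc_b$auc
  vd <- roc_a$var + roc_b$var - 2 * cv
  if (vd <= 1e-16) {
    warning("degenerate zero variance in AUC comparison")
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
    p <- if (abs(d) < 1e-12) 1 else 0
  } else {
    z <- d / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = roc_a$auc, auc_b = roc_b$auc, difference = d,
                 z = z, p = p, paired = paired),
            class = "ca_roc_test")
}

#' @export
print.ca_roc_test <- function(x, ...) {
  cat(sprintf("%s DeLong test: AUC %.3f vs %.3f (diff %+.3f), z = %.2f, p = %.3g\n",
              if (x$paired) "paired" else "unpaired",
              x$auc_a, x$auc_b, x$difference, x$z, x$p))
  invisible(x)
}

#' Class-stratified bootstrap confidence interval for the AUC
#'
#' Resamples cases and controls separately `B` times and returns the
#' percentile interval of the AUC.
#'
#' @param scores,labels as in [roc()].
#' @param B number of bootstrap resamples (default 2000).
#' @param seed RNG seed for reproducible intervals.
#' @param conf_level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(scores, labels, B = 2000, seed = 1,
                         conf_level = 0.95) {
  labels <- as.integer(labels)
  ci_idx <- which(labels == 1); co_idx <- which(labels == 0)
  if (length(ci_idx) < 2 || length(co_idx) < 2)
    ca_stop("bootstrap_ci() needs >= 2 members per class")
  ca_with_seed(seed, {
    aucs <- vapply(seq_len(B), function(b) {
      i1 <- sample(ci_idx, replace = TRUE)
      i0 <- sample(co_idx, replace = TRUE)
      ca_placements(c(scores[i1], scores[i0]),
                    c(rep(1L, length(i1)), rep(0L, length(i0))))$auc
    }, 0)
    alpha <- 1 - conf_level
    unname(quantile(aucs, c(alpha / 2, 1 - alpha / 2)))
  })
}
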