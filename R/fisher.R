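# Fisher exact association machinery for covariate-vs-fracture screens.

#' Two-sided Fisher exact test with the sample odds ratio
#'
#' The p-value is the conditional hypergeometric two-sided probability
#' (sum over tables, margins fixed, with probability <= that of the
#' observed table), as computed by [stats::fisher.test()]. The odds ratio
#' reported is the sample (cross-product) odds ratio `ad/bc` -- not the
#' conditional MLE -- with 0 / Inf for zero cells and NA when undefined.
#'
#' @param table2x2 2 x 2 matrix of non-negative integer counts,
#'   rows = exposure (0/1), columns = outcome (0/1).
#' @return list `odds_ratio`, `p`.
#' @export
fisher_exact <- function(table2x2) {
  tab <- as.matrix(table2x2)
  if (!all(dim(tab) == 2)) ca_stop("fisher_exact() needs a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    ca_stop("counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- if (a * d == 0 && b * c == 0) NA_real_
  else if (b * c == 0) Inf
  else (a * d) / (b * c)
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = p)
}

#' Covariate-fracture association table
#'
#' For every binarized covariate, cross-tabulates it against fracture
#' (rows with a missing covariate value are dropped per covariate) and
#' reports the sample odds ratio and two-sided Fisher exact p. Covariates
#' degenerate in the cohort (a single observed level) get `NA` odds ratio
#' and p = 1.
#'
#' @param binarized a `binarized_table` (or any data.frame of 0/1/NA
#'   covariates plus a `fracture` column).
#' @param ids optional `image_id` subset restricting the rows (e.g. a
#'   matched cohort).
#' @param alpha significance threshold used for the `significant` flag.
#' @return data.frame of class `association_table` (covariate, the 2x2
#'   counts, odds_ratio, p, significant) with the number of significant
#'   covariates in attribute `"n_significant"`.
#' @export
association_table <- function(binarized, ids = NULL, alpha = 0.05) {
  ca_check_cols(binarized, "fracture", "binarized")
  if (!is.null(ids))
    binarized <- binarized[binarized$image_id %in% ids, , drop = FALSE]
  skip <- c("image_id", "patient_id", "partition", "fracture")
  vars <- setdiff(names(binarized), skip)
  rows <- lapply(vars, function(v) {
    x <- binarized[[v]]; y <- binarized$fracture
    ok <- !is.na(x)
    x <- x[ok]; y <- y[ok]
    n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
    n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      or <- NA_real_; p <- 1
    } else {
      ft <- fisher_exact(matrix(c(n11, n10, n01, n00), 2, byrow = TRUE))
      or <- ft$odds_ratio; p <- ft$p
    }
    data.frame(covariate = v, n11 = n11, n10 = n10, n01 = n01, n00 = n00,
               odds_ratio = or, p = p, significant = !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_significant") <- sum(out$significant)
  class(out) <- c("association_table", "data.frame")
  out
}
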