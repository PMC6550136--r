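# Scalar-variable cleaning: feasibility filtering, nominal consolidation,
# train-median binarization, and imputation for matching/multimodal use.

#' Replace infeasible scalar values with NA
#'
#' Latency intervals outside [1, 1440] minutes (under a minute or over a
#' day) and BMI values above 60 are treated as data-entry artifacts and
#' blanked; every other field is untouched.
#'
#' @param cohort a `cohort_table` (or any data.frame with the latency /
#'   `bmi` columns; absent columns are skipped).
#' @return the cohort with infeasible entries set to `NA`.
#' @export
filter_infeasible <- function(cohort) {
  for (col in c("t_order_to_acq", "t_acq_to_prelim", "t_acq_to_final")) {
    if (!col %in% names(cohort)) next
    x <- cohort[[col]]
    x[!is.na(x) & (x < 1 | x > 1440)] <- NA
    cohort[[col]] <- x
  }
  if ("bmi" %in% names(cohort)) {
    x <- cohort$bmi
    x[!is.na(x) & x > 60] <- NA
    cohort$bmi <- x
  }
  cohort
}

#' Consolidate rare levels of a nominal column
#'
#' Keeps the `k` most frequent non-missing levels and maps every other
#' non-missing level to `"other_valid_entry"`; `NA` is preserved. Frequency
#' ties at rank `k` are broken in favour of the lexicographically smaller
#' level, so the result is deterministic.
#'
#' @param column factor or character vector.
#' @param k number of levels to keep (default 3, matching the staff-pool
#'   consolidation used for technicians and radiologists).
#' @return factor with at most `k + 1` levels.
#' @export
consolidate_nominal <- function(column, k = 3) {
  x <- as.character(column)
  # an existing consolidation bucket is passed through, not re-ranked,
  # so re-applying the rule is a no-op
  tab <- table(x[!is.na(x) & x != "other_valid_entry"])
  if (length(tab) <= k) {
    keep <- names(tab)
  } else {
    ord <- order(-as.numeric(tab), names(tab))
    keep <- names(tab)[ord][seq_len(k)]
  }
  out <- ifelse(is.na(x) | x %in% keep, x, "other_valid_entry")
  lv <- c(sort(keep), if (any(out == "other_valid_entry", na.rm = TRUE))
    "other_valid_entry")
  factor(out, levels = lv)
}

ca_top_levels <- function(x, k) {
  tab <- table(as.character(x[!is.na(x)]))
  if (length(tab) <= k) return(names(tab))
  ord <- order(-as.numeric(tab), names(tab))
  names(tab)[ord][seq_len(k)]
}

#' Binarize all PT and HP variables
#'
#' Coerces every explanatory variable to a 0/1/NA representation for the
#' logistic screens and association tables:
#' \itemize{
#'   \item continuous variables: indicator of exceeding the training-split
#'     median (ties, value == median, map to 0); medians are estimated on
#'     the training partition only and reused for test rows;
#'   \item `day_of_week`: weekend indicator;
#'   \item `view`: bilateral (1) versus lateral (0);
#'   \item `order_datetime`: indicator of the later half of the study
#'     window (> train-median timestamp);
#'   \item already-binary columns (`sex`, `fall`, `pain`, `priority`):
#'     passed through as 0/1;
#'   \item other categoricals: the two most frequent training levels kept
#'     as 0/1 (more frequent level = 0), all other levels set to `NA`.
#' }
#'
#' @param table a cohort data.frame containing a `partition` column.
#' @param roles variable roles, see [cohort_roles()].
#' @return data.frame of class `binarized_table` holding `image_id`,
#'   `patient_id`, `partition`, `fracture` and one 0/1/NA column per
#'   variable; the rule applied to each column is recorded in the
#'   `"rules"` attribute (a provenance map, serializable as a data
#'   dictionary via [binarization_dictionary()]).
#' @export
binarize <- function(table, roles = cohort_roles()) {
  ca_check_cols(table, c("partition", "fracture"), "table")
  train <- table$partition == "train"
  vars <- c(roles$pt, intersect(roles$hp, names(table)))
  out <- table[, intersect(c(roles$id, "fracture"), names(table)),
               drop = FALSE]
  rules <- list()
  for (v in vars) {
    x <- table[[v]]
    if (all(is.na(x))) ca_stop("cannot binarize all-missing column '%s'", v)
    if (is.numeric(x) && ca_is_binary(x)) {   # already 0/1 (incl. re-runs)
      b <- as.integer(x)
      rule <- "native binary"
    } else if (v == "day_of_week") {
      b <- as.integer(as.character(x) %in% c("Sat", "Sun"))
      b[is.na(x)] <- NA
      rule <- "weekend vs weekday"
    } else if (v == "view") {
      b <- as.integer(as.character(x) == "bilateral")
      b[is.na(x)] <- NA
      rule <- "bilateral vs lateral"
    } else if (v == "order_datetime") {
      t <- as.numeric(as.POSIXct(x, tz = "UTC"))
      med <- median(t[train], na.rm = TRUE)
      b <- as.integer(t > med)
      rule <- sprintf("> train-median timestamp (%s)",
                      format(as.POSIXct(med, tz = "UTC",
                                        origin = "1970-01-01")))
    } else if (is.numeric(x)) {
      med <- median(x[train], na.rm = TRUE)
      b <- as.integer(x > med)
      rule <- sprintf("> train median (%.4g)", med)
    } else {                              # categorical
      lv <- levels(factor(x))
      if (length(lv) <= 2) {
        b <- as.integer(factor(x, levels = lv)) - 1L
        rule <- sprintf("levels: %s=0, %s=1", lv[1],
                        if (length(lv) > 1) lv[2] else "-")
      } else {
        top <- ca_top_levels(x[train], 2)
        if (length(top) < 2)
          ca_stop("column '%s' has a single training level", v)
        b <- ifelse(as.character(x) == top[1], 0L,
                    ifelse(as.character(x) == top[2], 1L, NA_integer_))
        rule <- sprintf("top-2 train levels: %s=0, %s=1, rest NA",
                        top[1], top[2])
      }
    }
    out[[v]] <- b
    rules[[v]] <- rule
  }
  attr(out, "rules") <- rules
  class(out) <- c("binarized_table", "data.frame")
  out
}

#' Export the binarization provenance map as a data dictionary
#'
#' @param binarized a `binarized_table`.
#' @param path optional JSON file to write.
#' @return named list of rules (invisibly when `path` is given).
#' @export
binarization_dictionary <- function(binarized, path = NULL) {
  rules <- attr(binarized, "rules")
  if (!is.null(path)) {
    jsonlite::write_json(rules, path, auto_unbox = TRUE)
    return(invisible(rules))
  }
  rules
}

#' Impute missing entries for matching and multimodal modelling
#'
#' Categorical `NA`s become an explicit `"(Missing)"` level. Missing BMI is
#' predicted by a linear regression trained on the training-partition rows
#' with observed BMI, using the (already categorically-imputed,
#' median-filled) PT + HP covariates as predictors; rows the regression
#' cannot score fall back to the training median. Other continuous
#' variables are median-imputed (training median).
#'
#' @param table a cohort data.frame after [filter_infeasible()] (and, for
#'   staff columns, [consolidate_nominal()]).
#' @param roles variable roles, see [cohort_roles()].
#' @param bmi_predictors character vector of columns used in the BMI
#'   regression; default all PT + HP covariates except BMI itself.
#' @param bmi_method `"regression"` (default) or `"median"`.
#' @return list with `table` (no missing entries among PT/HP columns) and
#'   `bmi_model` (an `imputation_model`: coefficients, predictor set and
#'   fallback median).
#' @export
impute <- function(table, roles = cohort_roles(),
                   bmi_predictors = NULL, bmi_method = "regression") {
  ca_check_cols(table, "partition", "table")
  train <- table$partition == "train"
  vars <- c(roles$pt, intersect(roles$hp, names(table)))

  # categorical: explicit (Missing) level
  for (v in vars) {
    x <- table[[v]]
    if (is.numeric(x)) next
    x <- as.character(x)
    if (anyNA(x)) x[is.na(x)] <- "(Missing)"
    table[[v]] <- factor(x)
  }
  # continuous (other than bmi): train-median fill
  for (v in setdiff(vars, "bmi")) {
    x <- table[[v]]
    if (!is.numeric(x) || !anyNA(x)) next
    table[[v]][is.na(x)] <- median(x[train], na.rm = TRUE)
  }
  # order_datetime is a string column; leave as-is (dow/year cover it)

  bmi_model <- NULL
  if ("bmi" %in% names(table) && anyNA(table$bmi)) {
    preds <- bmi_predictors %||%
      setdiff(vars, c("bmi", "order_datetime"))
    preds <- intersect(preds, names(table))
    fallback <- median(table$bmi[train], na.rm = TRUE)
    obs <- train & !is.na(table$bmi)
    if (bmi_method == "regression" && sum(obs) >= length(preds) + 2) {
      fit <- lm(stats::reformulate(preds, "bmi"), data = table[obs, ])
      pred <- tryCatch(predict(fit, newdata = table),
                       error = function(e) rep(NA_real_, nrow(table)))
      miss <- is.na(table$bmi)
      table$bmi[miss] <- ifelse(is.na(pred[miss]), fallback, pred[miss])
      bmi_model <- structure(
        list(target = "bmi", predictors = preds,
             coefficients = coef(fit), fallback = fallback),
        class = "imputation_model")
    } else {
      if (bmi_method == "regression")
        warning("no usable complete-BMI training rows; median fallback")
      table$bmi[is.na(table$bmi)] <- fallback
      bmi_model <- structure(
        list(target = "bmi", predictors = character(),
             coefficients = NULL, fallback = fallback),
        class = "imputation_model")
    }
  }
  list(table = table, bmi_model = bmi_model)
}

#' Full tabular preparation for a cohort
#'
#' Convenience wrapper running the standard order: feasibility filter,
#' staff-pool consolidation (technician/radiologist to top-3 +
#' `other_valid_entry`), binarization (for screens/associations), and
#' imputation (for matching and multimodal models).
#'
#' @param cohort a `cohort_table`.
#' @param roles variable roles, see [cohort_roles()].
#' @return list with `filtered`, `binarized`, `imputed` (data.frames),
#'   `bmi_model`, and `dictionary`.
#' @export
prepare_cohort <- function(cohort, roles = cohort_roles()) {
  filt <- filter_infeasible(cohort)
  for (v in intersect(c("technician", "radiologist"), names(filt)))
    filt[[v]] <- consolidate_nominal(filt[[v]], k = 3)
  bin <- binarize(filt, roles)
  imp <- impute(filt, roles)
  list(filtered = filt, binarized = bin, imputed = imp$table,
       bmi_model = imp$bmi_model,
       dictionary = binarization_dictionary(bin))
}
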