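# Case-control matching by Gower dissimilarity, greedy without replacement.

#' Matching variable lists
#'
#' `random` uses no variables; `demographics` matches on age + sex; `pt`
#' on the five patient traits; `pt_hp` additionally on every
#' hospital-process covariate known at acquisition time (interpretation
#' latencies and the reading radiologist are post-acquisition and
#' excluded).
#'
#' @param level one of `"random"`, `"demographics"`, `"pt"`, `"pt_hp"`.
#' @param roles variable roles, see [cohort_roles()].
#' @return character vector of matching variables (empty for `random`).
#' @export
match_variables <- function(level = c("random", "demographics", "pt",
                                      "pt_hp"),
                            roles = cohort_roles()) {
  level <- match.arg(level)
  switch(level,
         random = character(),
         demographics = c("age", "sex"),
         pt = roles$pt,
         pt_hp = c(roles$pt, roles$hp_at_acquisition))
}

# per-variable ranges (continuous) from a reference pool
ca_gower_ranges <- function(data, vars) {
  r <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && !ca_is_binary(x))
      diff(range(x, na.rm = TRUE)) else NA_real_
  })
  setNames(r, vars)
}

#' Gower dissimilarity between two records
#'
#' Mean over variables of range-normalized absolute differences
#' (continuous) and mismatch indicators (categorical / binary).
#' Components where either value is missing are skipped and the mean is
#' renormalized over the observed components; if every component is
#' missing the pair is maximally unlike (dissimilarity 1). A zero range
#' makes a continuous component 0 (all values equal).
#'
#' @param a,b one-row data.frames.
#' @param vars variables to compare.
#' @param ranges optional named list of continuous ranges (defaults to
#'   ranges computed from the two records; in matching, ranges come from
#'   the test-partition pool).
#' @return dissimilarity in [0, 1].
#' @export
gower_distance <- function(a, b, vars, ranges = NULL) {
  if (!length(vars)) ca_stop("vars must be non-empty")
  d <- 0; k <- 0
  for (v in vars) {
    xa <- a[[v]]; xb <- b[[v]]
    if (is.na(xa) || is.na(xb)) next
    if (is.numeric(xa) && !is.null(ranges) && !is.na(ranges[[v]])) {
      rg <- ranges[[v]]
      d <- d + if (rg > 0) min(abs(xa - xb) / rg, 1) else 0
    } else if (is.numeric(xa) && is.null(ranges)) {
      rg <- abs(xa - xb)  # no pool: degenerate two-point range
      d <- d + as.numeric(rg > 0)
    } else {
      d <- d + as.numeric(as.character(xa) != as.character(xb))
    }
    k <- k + 1
  }
  if (k == 0) return(1)
  d / k
}

# case x control Gower matrix (vectorized over controls)
ca_gower_matrix <- function(cases, controls, vars, ranges) {
  D <- matrix(0, nrow(cases), nrow(controls))
  K <- matrix(0, nrow(cases), nrow(controls))
  for (v in vars) {
    xc <- cases[[v]]; xo <- controls[[v]]
    num <- is.numeric(xc) && !is.na(ranges[[v]])
    for (i in seq_len(nrow(cases))) {
      if (is.na(xc[i])) next
      obs <- !is.na(xo)
      if (num) {
        rg <- ranges[[v]]
        dv <- if (rg > 0) pmin(abs(xc[i] - xo) / rg, 1) else 0 * xo
      } else {
        dv <- as.numeric(as.character(xo) != as.character(xc[i]))
      }
      D[i, obs] <- D[i, obs] + dv[obs]
      K[i, obs] <- K[i, obs] + 1
    }
  }
  out <- ifelse(K > 0, D / pmax(K, 1), 1)
  out
}

#' Build a case-control test cohort by matching
#'
#' Downsamples the non-fracture radiographs of the test partition: for
#' `level = "random"` one uniformly sampled control per case; otherwise
#' cases are processed in seed-shuffled order and each is assigned its
#' minimum-Gower unused control (greedy, without replacement), ties broken
#' by the smallest control `image_id`. Matching distances use the raw-scale
#' (imputed) covariates; continuous ranges come from the test partition,
#' the pool being matched from.
#'
#' @param data imputed cohort data.frame (the test partition is selected
#'   internally when a `partition` column is present).
#' @param level match depth, see [match_variables()].
#' @param seed RNG seed for the case processing order / random controls.
#' @param vars optional explicit matching variables (overrides `level`).
#' @param roles variable roles, see [cohort_roles()].
#' @return object of class `matched_cohort`: `pairs` (case_id, control_id,
#'   dissimilarity), `records` (the matched subset, cases + controls),
#'   `level`, `vars`, `seed`, `n_unmatched`.
#' @export
match_controls <- function(data, level = "random", seed = 1, vars = NULL,
                           roles = cohort_roles()) {
  if ("partition" %in% names(data))
    data <- data[data$partition == "test", , drop = FALSE]
  ca_check_cols(data, c("image_id", "fracture"), "data")
  vars <- vars %||% match_variables(level, roles)
  if (length(vars)) ca_check_cols(data, vars, "data")
  cases <- data[data$fracture == 1, , drop = FALSE]
  controls <- data[data$fracture == 0, , drop = FALSE]
  if (nrow(cases) == 0) ca_stop("no fracture cases in the test partition")
  if (nrow(controls) < nrow(cases))
    warning(sprintf("only %d controls for %d cases; pairing what we can",
                    nrow(controls), nrow(cases)))

  if (!length(vars)) {
    pairs <- ca_with_seed(seed, {
      k <- min(nrow(cases), nrow(controls))
      sel <- sample(nrow(controls), k)
      data.frame(case_id = cases$image_id[seq_len(k)],
                 control_id = controls$image_id[sel],
                 dissimilarity = NA_real_, stringsAsFactors = FALSE)
    })
  } else {
    ranges <- ca_gower_ranges(data, vars)
    D <- ca_gower_matrix(cases, controls, vars, ranges)
    ord <- ca_with_seed(seed, sample(nrow(cases)))
    used <- rep(FALSE, nrow(controls))
    ctrl_order <- order(controls$image_id)  # lexicographic tie-break
    pairs <- vector("list", nrow(cases))
    for (i in ord) {
      if (all(used)) break
      dd <- D[i, ]
      dd[used] <- Inf
      best <- min(dd)
      cand <- which(dd == best)
      pick <- cand[order(controls$image_id[cand])][1]
      used[pick] <- TRUE
      pairs[[i]] <- data.frame(case_id = cases$image_id[i],
                               control_id = controls$image_id[pick],
                               dissimilarity = best,
                               stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
  }
  n_unmatched <- nrow(cases) - nrow(pairs)
  if (n_unmatched > 0)
    message(sprintf("%d case(s) left unmatched (control pool exhausted)",
                    n_unmatched))
  keep <- c(pairs$case_id, pairs$control_id)
  records <- data[match(keep, data$image_id), , drop = FALSE]
  structure(list(pairs = pairs, records = records, level = level,
                 vars = vars, seed = seed, n_unmatched = n_unmatched),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("matched_cohort (%s): %d pairs, %d unmatched, mean Gower %.3f\n",
              x$level, nrow(x$pairs), x$n_unmatched,
              mean(x$pairs$dissimilarity)))
  invisible(x)
}

#' Cohort characteristics summary
#'
#' One column per cohort with the standard row set: number of radiographs,
#' patients, scanners in use, age mean (SD), female frequency, fracture
#' frequency, BMI mean (SD), fall and pain frequencies.
#'
#' @param cohorts named list whose elements are data.frames (cross-
#'   sectional sets) or `matched_cohort` objects.
#' @return data.frame, rows = characteristics, columns = cohorts.
#' @export
cohort_summary <- function(cohorts) {
  one <- function(d) {
    if (inherits(d, "matched_cohort")) d <- d$records
    pct <- function(x) 100 * mean(x == 1 | x == "F", na.rm = TRUE)
    c(n_radiographs = nrow(d),
      n_patients = length(unique(d$patient_id)),
      n_scanners = length(unique(as.character(d$scanner_model))),
      age_mean = mean(d$age, na.rm = TRUE),
      age_sd = sd(d$age, na.rm = TRUE),
      female_pct = 100 * mean(d$sex == "F", na.rm = TRUE),
      fracture_n = sum(d$fracture == 1),
      fracture_pct = 100 * mean(d$fracture == 1),
      bmi_mean = mean(d$bmi, na.rm = TRUE),
      bmi_sd = sd(d$bmi, na.rm = TRUE),
      fall_pct = 100 * mean(d$fall == 1, na.rm = TRUE),
      pain_pct = 100 * mean(d$pain == 1, na.rm = TRUE))
  }
  out <- vapply(cohorts, one, numeric(12))
  as.data.frame(round(out, 2))
}

#' Mean absolute standardized case-control difference over variables
#'
#' Balance diagnostic: for each matching variable, the absolute
#' standardized difference in means (continuous) or proportions (binary /
#' categorical levels) between cases and controls, averaged.
#'
#' @param matched a `matched_cohort`.
#' @param vars variables to assess (default: the cohort's matching
#'   variables, or age/sex when it was randomly sampled).
#' @return mean absolute standardized difference.
#' @export
balance_smd <- function(matched, vars = NULL) {
  d <- matched$records
  vars <- vars %||% (if (length(matched$vars)) matched$vars
                     else c("age", "sex"))
  grp <- d$fracture == 1
  smd_one <- function(x) {
    if (is.numeric(x)) {
      s <- sqrt((var(x[grp], na.rm = TRUE) + var(x[!grp], na.rm = TRUE)) / 2)
      if (!is.finite(s) || s == 0) return(0)
      abs(mean(x[grp], na.rm = TRUE) - mean(x[!grp], na.rm = TRUE)) / s
    } else {
      lv <- unique(as.character(x[!is.na(x)]))
      if (length(lv) < 2) return(0)
      mean(vapply(lv, function(l) {
        p1 <- mean(x[grp] == l, na.rm = TRUE)
        p0 <- mean(x[!grp] == l, na.rm = TRUE)
        s <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
        if (s == 0) 0 else abs(p1 - p0) / s
      }, 0))
    }
  }
  mean(vapply(vars, function(v) smd_one(d[[v]]), 0))
}
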