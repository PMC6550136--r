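# Synthetic observational cohort generator.
#
# Causal structure: PT -> fracture (logistic), (fracture, PT) -> HP triage,
# (HP, PT, fracture) -> pixels (see render.R). Scanner fleet and staff pools
# are fixed institution-level facts shared by every cohort.

ca_scanner_fleet <- function() {
  data.frame(
    scanner_model = c("FX-100p", "FX-200", "GE-AMX4", "GE-DR600",
                      "KON-CS7", "PHI-DIG5"),
    scanner_manufacturer = c("Fujifilm", "Fujifilm", "GE", "GE",
                             "Konica", "Philips"),
    # pixel signature parameters (used by render.R)
    border_frac = c(0.10, 0.02, 0.06, 0.00, 0.04, 0.08),
    contrast    = c(1.30, 0.85, 1.10, 1.00, 0.75, 1.20),
    grain       = c(1.60, 0.80, 1.20, 1.00, 0.70, 1.40),
    offset      = c(0.06, -0.04, 0.02, 0.00, -0.06, 0.04),
    dose_base   = c(2.2, 3.2, 2.6, 3.0, 3.4, 2.8),
    stringsAsFactors = FALSE)
}

ca_departments <- c("ED", "inpatient", "outpatient", "NA_dept")
ca_views <- c("ap_left", "ap_right", "bilateral", "frog_leg")
ca_technicians <- paste0("tech_", sprintf("%02d", 1:8))
ca_radiologists <- paste0("rad_", sprintf("%02d", 1:10))

# log-weights of scanner use by department (rows = departments, cols = fleet)
ca_scanner_dept_logw <- function() {
  m <- rbind(
    ED         = c(1.6, 0.2, 1.2, 0.3, 0.1, 0.4),
    inpatient  = c(0.8, 0.2, 1.5, 0.6, 0.2, 0.4),
    outpatient = c(0.0, 1.3, 0.2, 1.2, 1.0, 0.9),
    NA_dept    = c(0.5, 0.8, 0.6, 0.9, 0.7, 0.9))
  colnames(m) <- ca_scanner_fleet()$scanner_model
  m
}

#' Simulate a confounded radiograph cohort
#'
#' Draws patients with traits (age, sex, BMI, fall, pain), assigns fracture
#' status from a logistic model on those traits (intercept calibrated by
#' bisection so the radiograph-level prevalence matches
#' `config$prevalence`), then triages each radiograph through
#' hospital-process variables whose distributions shift with fracture status
#' and patient traits. The train/test partition is patient-stratified
#' (no patient appears in both partitions).
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `cohort_table`, one row per radiograph,
#'   with identifier columns (`image_id`, `patient_id`, `partition`), the
#'   fracture label, the 5 PT columns, and the 14 HP columns (including the
#'   `day_of_week` / `year` fields derived from `order_datetime`). The
#'   generating config is attached as attribute `"config"`.
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 200, seed = 7))
#' mean(co$fracture)   # ~0.03
#' @export
simulate_cohort <- function(config = sim_config()) {
  config <- validate_sim_config(unclass(config))
  ca_with_seed(config$seed, {
    n_pat <- as.integer(config$n_patients)
    pat_id <- sprintf("pt%05d", seq_len(n_pat))

    ## --- patient traits ------------------------------------------------
    age <- pmin(pmax(rnorm(n_pat, 62, 22), 18), 100)
    sex <- factor(ifelse(runif(n_pat) < 0.65, "F", "M"), levels = c("F", "M"))
    bmi_true <- pmax(rnorm(n_pat, 29 - 0.04 * (age - 60), 6), 14)
    # occasional data-entry error producing an infeasible value (> 60)
    err <- runif(n_pat) < 0.002
    bmi_true[err] <- bmi_true[err] + 45
    fall <- rbinom(n_pat, 1, plogis(-1.75 + 0.035 * (age - 60)))
    pain <- rbinom(n_pat, 1, plogis(0.0 + 0.004 * (age - 60)))

    ## --- radiograph counts (per-patient) --------------------------------
    n_img <- 1L + rpois(n_pat, max(config$images_per_patient_mean - 1, 0))

    ## --- fracture: logistic on PT, intercept calibrated ------------------
    b <- config$pt_coefs
    lp <- b["age"] * (age - 60) / 10 + b["sexF"] * (sex == "F") +
      b["bmi"] * (25 - pmin(bmi_true, 60)) / 5 + b["fall"] * fall +
      b["pain"] * pain
    # image-weighted expected prevalence == target
    f <- function(a) sum(n_img * plogis(a + lp)) / sum(n_img) -
      config$prevalence
    lo <- -20; hi <- 5
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    intercept <- (lo + hi) / 2
    fracture_pat <- rbinom(n_pat, 1, plogis(intercept + lp))

    ## --- partition: patient-stratified 3:1 ------------------------------
    test_pat <- sample(n_pat, round(n_pat * config$test_fraction))
    partition_pat <- rep("train", n_pat)
    partition_pat[test_pat] <- "test"

    ## --- expand to radiographs ------------------------------------------
    pi <- rep(seq_len(n_pat), n_img)
    n <- length(pi)
    tab <- data.frame(
      image_id = sprintf("img%06d", seq_len(n)),
      patient_id = pat_id[pi],
      partition = partition_pat[pi],
      fracture = fracture_pat[pi],
      age = round(age[pi], 1),
      sex = sex[pi],
      bmi = round(bmi_true[pi], 1),
      fall = fall[pi],
      pain = pain[pi],
      stringsAsFactors = FALSE)

    ## --- hospital-process triage ----------------------------------------
    g <- config$triage_coefs
    fr <- tab$fracture
    # order priority: acute presentations (fracture, fall) get stat orders
    tab$priority <- rbinom(n, 1, plogis(-1.1 + g["priority"] * fr +
                                          0.4 * tab$fall))
    # department: fracture and falls route to the ED / inpatient floors
    dep_base <- log(c(ED = 0.34, inpatient = 0.18, outpatient = 0.15,
                      NA_dept = 0.33))
    dep_score <- matrix(dep_base, n, 4, byrow = TRUE)
    dep_score[, 1] <- dep_score[, 1] + g["department"] * fr + 0.5 * tab$fall
    dep_score[, 2] <- dep_score[, 2] + 0.4 * g["department"] / 1.5 * fr +
      0.006 * (tab$age - 60)
    tab$department <- ca_sample_softmax(dep_score, ca_departments)

    # order datetime: 2008-2016 with mild weekend excess for fractures
    year <- sample(2008:2016, n, replace = TRUE)
    p_wknd <- plogis(qlogis(2 / 7) + g["weekend"] * fr)
    weekend <- rbinom(n, 1, p_wknd)
    dow_num <- ifelse(weekend == 1, sample(c(6, 7), n, replace = TRUE),
                      sample(1:5, n, replace = TRUE))
    # construct an actual date in `year` with that day-of-week
    base <- as.Date(sprintf("%d-01-01", year))
    off <- (dow_num - as.integer(format(base, "%u"))) %% 7 +
      7 * sample(0:49, n, replace = TRUE)
    date <- pmin(base + off, as.Date(sprintf("%d-12-31", year)))
    hour <- pmin(23, pmax(0, round(rnorm(n, 13 - 2 * tab$priority, 5))))
    tab$order_datetime <- sprintf("%s %02d:%02d:00", format(date), hour,
                                  sample(0:59, n, replace = TRUE))
    tab$day_of_week <- factor(
      c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[dow_num],
      levels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
    tab$year <- year

    # scanner: department fleet mix + portable-unit shift for fractures
    # + year drift (units phased in/out over the study window)
    fleet <- ca_scanner_fleet()
    logw <- ca_scanner_dept_logw()
    sc_score <- logw[as.character(tab$department), , drop = FALSE]
    sc_score[, "FX-100p"] <- sc_score[, "FX-100p"] + g["scanner"] * fr
    drift <- (year - 2012) / 4
    sc_score[, "FX-200"] <- sc_score[, "FX-200"] + 2.0 * drift
    sc_score[, "KON-CS7"] <- sc_score[, "KON-CS7"] - 2.0 * drift
    sc_score[, "PHI-DIG5"] <- sc_score[, "PHI-DIG5"] + 1.0 * drift
    tab$scanner_model <- ca_sample_softmax(sc_score, fleet$scanner_model)
    tab$scanner_manufacturer <- factor(
      fleet$scanner_manufacturer[match(tab$scanner_model,
                                       fleet$scanner_model)],
      levels = unique(fleet$scanner_manufacturer))

    # view: suspected fractures get dedicated unilateral / frog-leg views
    vw_base <- log(c(ap_left = 0.28, ap_right = 0.28, bilateral = 0.34,
                     frog_leg = 0.10))
    vw_score <- matrix(vw_base, n, 4, byrow = TRUE)
    vw_score[, 3] <- vw_score[, 3] - g["view"] * fr
    vw_score[, 4] <- vw_score[, 4] + 0.5 * g["view"] * fr
    tab$view <- ca_sample_softmax(vw_score, ca_views)

    # staff pools differ by department shift patterns
    tec_score <- matrix(0, n, length(ca_technicians))
    tec_score[, 1:3] <- tec_score[, 1:3] + 1.0 * (tab$department == "ED")
    tec_score[, 4:6] <- tec_score[, 4:6] +
      0.8 * (tab$department == "outpatient")
    tab$technician <- ca_sample_softmax(tec_score, ca_technicians)
    rad_score <- matrix(0, n, length(ca_radiologists))
    rad_score[, 1:4] <- rad_score[, 1:4] + 0.9 * (tab$department == "ED")
    tab$radiologist <- ca_sample_softmax(rad_score, ca_radiologists)

    # radiation dose: scanner calibration + body habitus
    dbase <- fleet$dose_base[match(tab$scanner_model, fleet$scanner_model)]
    tab$radiation_dose <- round(rlnorm(n, log(dbase) +
                                         0.012 * (tab$bmi - 28), 0.30), 3)

    # latencies (minutes); stat orders move faster. Log-normal tails land a
    # small fraction outside the feasible [1, 1440] window on purpose.
    acute <- g["latency"] * (tab$priority + 0.5 * fr)
    tab$t_order_to_acq <- round(rlnorm(n, log(55) - acute, 1.1), 1)
    tab$t_acq_to_prelim <- round(rlnorm(n, log(120) - 0.6 * acute, 1.2), 1)
    tab$t_acq_to_final <- round(tab$t_acq_to_prelim +
                                  rlnorm(n, log(240), 0.8), 1)

    ## --- missingness ------------------------------------------------------
    tab$bmi[runif(n) < config$bmi_missing_rate] <- NA

    class(tab) <- c("cohort_table", "data.frame")
    attr(tab, "config") <- config
    tab
  })
}

#' Variable roles in a cohort table
#'
#' @return named list with the identifier, PT, HP, and derived column names
#'   used throughout the pipeline; `hp_at_acquisition` lists the HP columns
#'   known at image-acquisition time (interpretation latencies and the
#'   reading radiologist are only known afterwards and are excluded from
#'   matching and explanatory models).
#' @export
cohort_roles <- function() {
  list(
    id = c("image_id", "patient_id", "partition"),
    label = "fracture",
    pt = c("age", "sex", "bmi", "fall", "pain"),
    hp = c("department", "scanner_model", "scanner_manufacturer", "view",
           "order_datetime", "day_of_week", "year", "priority",
           "technician", "radiologist", "radiation_dose",
           "t_order_to_acq", "t_acq_to_prelim", "t_acq_to_final"),
    hp_at_acquisition = c("department", "scanner_model",
                          "scanner_manufacturer", "view", "day_of_week",
                          "year", "priority", "technician",
                          "radiation_dose", "t_order_to_acq"),
    continuous = c("age", "bmi", "radiation_dose", "t_order_to_acq",
                   "t_acq_to_prelim", "t_acq_to_final", "year"))
}
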