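#' Simulation configuration for a synthetic radiograph cohort
#'
#' Encodes the structural-causal model behind [simulate_cohort()]: patient
#' traits (PT) drive fracture risk through a logistic model; fracture status
#' and PT drive hospital-process (HP) triage (department, scanner, order
#' priority, view, timing); and HP/PT variables leave signatures in the
#' rendered pixels with tunable strengths. `beta_direct` is the contrast of
#' the direct fracture signature in the image: at 0 the pixels are
#' conditionally independent of fracture given (PT, HP), so any image-model
#' performance is confounder-mediated by construction.
#'
#' @param n_patients number of patients. Each patient contributes
#'   `1 + Poisson(images_per_patient_mean - 1)` radiographs, mirroring the
#'   2-3 views per study typical of hip series.
#' @param images_per_patient_mean mean radiographs per patient (>= 1).
#' @param seed integer seed; identical config + seed gives a byte-identical
#'   cohort and pixel data.
#' @param prevalence target marginal fracture prevalence over radiographs.
#'   The logit intercept is calibrated by bisection against the drawn PT
#'   distribution so the expected prevalence equals this value.
#' @param pt_coefs named numeric vector of PT -> fracture log-odds
#'   coefficients: `age` (per decade over 60), `sexF`, `bmi` (per 5 kg/m^2
#'   below 25), `fall`, `pain`. Signs follow hip-fracture epidemiology
#'   (older, lower-BMI, post-fall patients at higher risk; pain is a
#'   non-specific indication and is coded negative).
#' @param triage_coefs named numeric vector of fracture -> HP triage
#'   log-odds shifts: `priority`, `department` (towards ED), `scanner`
#'   (towards the portable ED scanner), `view` (towards unilateral views),
#'   `weekend`, `latency` (log-scale reduction of waiting times for
#'   priority/fracture studies). Setting all to 0 removes the HP pathway.
#' @param image_strengths named non-negative vector of pixel-signature
#'   strengths: `scanner` (border/contrast/grain), `view` (side-marker
#'   placement), `bmi` (brightness and soft-tissue mottle), `age`
#'   (bone-pattern contrast falls with age, an osteopenia analogue),
#'   `dose` (noise scaling). 0 removes the corresponding pixel pathway.
#' @param beta_direct non-negative contrast of the fracture line signature.
#' @param bmi_missing_rate probability a recorded BMI is missing
#'   (missing-completely-at-random).
#' @param image_size square image side in pixels (configurable up to 299).
#' @param test_fraction fraction of patients assigned to the test partition
#'   (patient-stratified; default 1/4 for a 3:1 train:test split).
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [render_image()]
#' @export
sim_config <- function(n_patients = 4000,
                       images_per_patient_mean = 2.6,
                       seed = 1,
                       prevalence = 0.03,
                       pt_coefs = c(age = 0.40, sexF = 0.10, bmi = 0.45,
                                    fall = 0.80, pain = -0.70),
                       triage_coefs = c(priority = 2.2, department = 2.2,
                                        scanner = 2.0, view = 0.8,
                                        weekend = 0.3, latency = 0.8),
                       image_strengths = c(scanner = 1.0, view = 1.0,
                                           bmi = 0.3, age = 0.6,
                                           dose = 0.5),
                       beta_direct = 0,
                       bmi_missing_rate = 0.10,
                       image_size = 96,
                       test_fraction = 0.25) {
  cfg <- list(n_patients = n_patients,
              images_per_patient_mean = images_per_patient_mean,
              seed = seed, prevalence = prevalence,
              pt_coefs = pt_coefs, triage_coefs = triage_coefs,
              image_strengths = image_strengths, beta_direct = beta_direct,
              bmi_missing_rate = bmi_missing_rate, image_size = image_size,
              test_fraction = test_fraction)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_num <- function(field, lo = -Inf, hi = Inf, len = 1L) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != len || anyNA(x) || any(x < lo) ||
        any(x > hi))
      ca_stop("invalid sim_config field '%s'", field)
  }
  chk_num("n_patients", lo = 2)
  chk_num("images_per_patient_mean", lo = 1)
  chk_num("seed")
  chk_num("prevalence", lo = 1e-4, hi = 0.5)
  chk_num("beta_direct", lo = 0)
  chk_num("bmi_missing_rate", lo = 0, hi = 1)
  chk_num("image_size", lo = 16, hi = 1024)
  chk_num("test_fraction", lo = 0.05, hi = 0.95)
  need <- function(field, nm, nonneg = FALSE) {
    x <- cfg[[field]]
    if (!is.numeric(x) || anyNA(x) || !all(nm %in% names(x)))
      ca_stop("invalid sim_config field '%s' (needs names: %s)", field,
              paste(nm, collapse = ", "))
    if (nonneg && any(x < 0))
      ca_stop("invalid sim_config field '%s' (strengths must be >= 0)", field)
  }
  need("pt_coefs", c("age", "sexF", "bmi", "fall", "pain"))
  need("triage_coefs", c("priority", "department", "scanner", "view",
                         "weekend", "latency"))
  need("image_strengths", c("scanner", "view", "bmi", "age", "dose"),
       nonneg = TRUE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_patients, "patients, ~",
      round(x$n_patients * x$images_per_patient_mean), "radiographs,",
      "prevalence", x$prevalence, "\n")
  cat("  beta_direct =", x$beta_direct, "| image_size =", x$image_size,
      "| seed =", x$seed, "\n")
  invisible(x)
}
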