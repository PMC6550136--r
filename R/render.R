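# Synthetic radiograph rendering.
#
# Pixels are a sum of designed signatures, not anatomy: a fixed
# pelvis-like base pattern, per-scanner collimation border / contrast /
# grain / offset, a view-dependent side marker, BMI-driven brightness and
# soft-tissue mottle, dose-driven quantum noise, and (optionally) a thin
# dark fracture line with contrast beta_direct. With beta_direct = 0 the
# pixel distribution is a function of (PT, HP) only, so pixels carry no
# information about fracture beyond the confounders.

# fixed base pattern: femoral-head blob + shaft ridge
ca_base_pattern <- function(size) {
  x <- matrix(seq_len(size), size, size)
  y <- t(x)
  cx <- 0.45 * size; cy <- 0.40 * size
  blob <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * (0.26 * size)^2))
  ridge <- exp(-((y - 0.62 * size)^2) / (2 * (0.05 * size)^2)) *
    (x > 0.35 * size)
  0.5 + 0.22 * blob + 0.10 * ridge - 0.12
}

# boolean masks reused across images of one size
ca_render_masks <- function(size) {
  fleet <- ca_scanner_fleet()
  border <- lapply(fleet$border_frac, function(bf) {
    w <- round(bf * size)
    m <- matrix(FALSE, size, size)
    if (w > 0) {
      m[seq_len(w), ] <- TRUE; m[size - seq_len(w) + 1, ] <- TRUE
      m[, seq_len(w)] <- TRUE; m[, size - seq_len(w) + 1] <- TRUE
    }
    m
  })
  names(border) <- fleet$scanner_model
  mark <- function(r0, c0) {
    m <- matrix(FALSE, size, size)
    s <- max(3, round(0.09 * size))
    m[r0:(r0 + s - 1), c0:(c0 + s - 1)] <- TRUE
    m
  }
  s <- max(3, round(0.09 * size))
  marker <- list(
    ap_left = mark(2, 2),
    ap_right = mark(2, size - s - 1),
    bilateral = mark(2, 2) | mark(2, size - s - 1),
    frog_leg = mark(round(0.25 * size), 2))
  # fracture line: diagonal segment across the femoral neck region
  fr <- matrix(FALSE, size, size)
  t0 <- round(0.40 * size); t1 <- round(0.68 * size)
  for (t in t0:t1) {
    r <- round(0.33 * size + 0.5 * (t - t0))
    fr[r + 0:2, t] <- TRUE
  }
  list(border = border, marker = marker, fracture = fr,
       base = ca_base_pattern(size))
}

.ca_mask_cache <- new.env(parent = emptyenv())
ca_masks <- function(size) {
  key <- as.character(size)
  if (is.null(.ca_mask_cache[[key]]))
    .ca_mask_cache[[key]] <- ca_render_masks(size)
  .ca_mask_cache[[key]]
}

# render one image as a numeric vector (column-major pixels in [0, 1])
ca_render_vec <- function(record, config, masks,
                          fleet = ca_scanner_fleet()) {
  size <- config$image_size
  w <- config$image_strengths
  si <- match(as.character(record$scanner_model), fleet$scanner_model)
  if (is.na(si)) ca_stop("unknown scanner_model '%s'", record$scanner_model)
  bmi <- record$bmi
  if (is.na(bmi)) bmi <- 28
  age <- record$age
  if (is.null(age) || is.na(age)) age <- 62
  dose <- max(as.numeric(record$radiation_dose), 0.5)

  ca_with_seed(ca_hash32(config$seed, record$image_id), {
    # bone-pattern contrast falls with age (osteopenia analogue),
    # saturating in the elderly range
    bone <- max(1 - w["age"] * 0.9 * min((age - 40) / 60, 0.5), 0.15)
    X <- (masks$base - 0.5) * bone *
      (1 + w["scanner"] * (fleet$contrast[si] - 1)) +
      0.5 + w["scanner"] * fleet$offset[si] +
      w["bmi"] * 0.15 * (bmi - 28) / 7
    # soft-tissue mottle: low-frequency field, amplitude grows with BMI
    k <- max(4, size %/% 8)
    low <- matrix(rnorm(k * k), k, k)
    up <- ceiling(size / k)
    ridx <- rep(seq_len(k), each = up)[seq_len(size)]
    low_up <- low[ridx, ridx]
    a_lo <- 0.05 * (1 + w["bmi"] * pmax(bmi - 24, 0) / 10)
    # quantum noise: scanner grain, reduced at higher dose
    a_hi <- 0.10 * fleet$grain[si]^w["scanner"] *
      (fleet$dose_base[si] / dose)^(0.5 * w["dose"])
    X <- X + a_lo * low_up + a_hi * matrix(rnorm(size * size), size, size)
    bm <- masks$border[[si]]
    X[bm] <- X[bm] * (1 - 0.9 * w["scanner"]) + 0.9 * w["scanner"] * 0.05
    vm <- masks$marker[[as.character(record$view)]]
    X[vm] <- X[vm] + w["view"] * 0.45
    if (config$beta_direct > 0 && record$fracture == 1)
      X[masks$fracture] <- X[masks$fracture] - config$beta_direct
    pmin(pmax(as.vector(X), 0), 1)
  })
}

#' Render one synthetic radiograph
#'
#' Deterministic given `(record, config)`: the per-image RNG stream is seeded
#' by a hash of the global seed and `image_id`, so rendering order and
#' parallelism do not change pixels.
#'
#' @param record one-row data.frame (a `cohort_table` row).
#' @param config the [sim_config()] the cohort was generated with.
#' @return `image_size` x `image_size` numeric matrix with values in [0, 1].
#' @export
render_image <- function(record, config) {
  if (nrow(record) != 1) ca_stop("render_image() takes a single record")
  ca_check_cols(record, c("image_id", "scanner_model", "view", "bmi",
                          "age", "radiation_dose", "fracture"), "record")
  size <- config$image_size
  matrix(ca_render_vec(record, config, ca_masks(size)), size, size)
}

#' Render all radiographs of a cohort
#'
#' @param cohort a `cohort_table`.
#' @param config the generating [sim_config()]; defaults to the config
#'   attached to `cohort`.
#' @return numeric matrix, one row per radiograph (rownames = `image_id`),
#'   columns = column-major pixels.
#' @export
render_images <- function(cohort, config = attr(cohort, "config")) {
  if (is.null(config)) ca_stop("no config attached to cohort; pass one")
  size <- config$image_size
  masks <- ca_masks(size)
  out <- matrix(0, nrow(cohort), size * size,
                dimnames = list(cohort$image_id, NULL))
  # pre-extract columns: per-row data.frame subsetting is the bottleneck
  cols <- list(image_id = cohort$image_id,
               scanner_model = as.character(cohort$scanner_model),
               view = as.character(cohort$view),
               bmi = cohort$bmi,
               age = cohort$age,
               radiation_dose = cohort$radiation_dose,
               fracture = cohort$fracture)
  fleet <- ca_scanner_fleet()
  for (i in seq_len(nrow(cohort)))
    out[i, ] <- ca_render_vec(lapply(cols, `[`, i), config, masks, fleet)
  attr(out, "image_size") <- size
  out
}
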