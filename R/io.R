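# Cohort persistence: CSV metadata + PNG images + JSON config sidecar.

#' Write a cohort to disk
#'
#' Writes `metadata.csv` (one row per radiograph, RFC-4180, UTF-8, header),
#' `sim_config.json` (the generating configuration, when attached), and --
#' optionally -- 8-bit grayscale PNGs named `<image_id>.png` under
#' `dir/images/`.
#'
#' @param cohort a `cohort_table`.
#' @param dir output directory (created if needed).
#' @param images optional matrix from [render_images()]; `NULL` skips PNGs.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, images = NULL) {
  if (nrow(cohort) == 0) ca_stop("refusing to write an empty cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) ca_stop("cannot create directory '%s'", dir)
  utils::write.csv(as.data.frame(cohort), file.path(dir, "metadata.csv"),
                   row.names = FALSE, na = "")
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    ser <- lapply(unclass(cfg), function(v)
      if (!is.null(names(v))) as.list(v) else v)  # keep coefficient names
    jsonlite::write_json(ser, file.path(dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(images)) {
    idir <- file.path(dir, "images")
    dir.create(idir, showWarnings = FALSE)
    size <- attr(images, "image_size") %||% sqrt(ncol(images))
    for (i in seq_len(nrow(images)))
      png::writePNG(matrix(images[i, ], size, size),
                    file.path(idir, paste0(rownames(images)[i], ".png")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `metadata.csv` (and optionally
#'   `sim_config.json`).
#' @return a `cohort_table` with factor levels and column types restored.
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "metadata.csv")
  if (!file.exists(path)) ca_stop("no metadata.csv under '%s'", dir)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  fleet <- ca_scanner_fleet()
  relevel_if <- function(col, levels) {
    if (col %in% names(tab)) tab[[col]] <<- factor(tab[[col]], levels = levels)
  }
  relevel_if("sex", c("F", "M"))
  relevel_if("department", ca_departments)
  relevel_if("scanner_model", fleet$scanner_model)
  relevel_if("scanner_manufacturer", unique(fleet$scanner_manufacturer))
  relevel_if("view", ca_views)
  relevel_if("day_of_week", c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  relevel_if("technician", ca_technicians)
  relevel_if("radiologist", ca_radiologists)
  cfg_path <- file.path(dir, "sim_config.json")
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    for (f in c("pt_coefs", "triage_coefs", "image_strengths"))
      cfg[[f]] <- unlist(cfg[[f]])
    attr(tab, "config") <- validate_sim_config(cfg)
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Read user-supplied grayscale images for a cohort
#'
#' Accepts any directory of `<image_id>.png` files (8- or 16-bit grayscale;
#' RGB images are averaged to one channel).
#'
#' @param cohort a `cohort_table` (its `image_id` column names the files).
#' @param dir directory of PNG files.
#' @return list of numeric matrices named by `image_id`.
#' @export
read_images <- function(cohort, dir) {
  out <- lapply(cohort$image_id, function(id) {
    f <- file.path(dir, paste0(id, ".png"))
    if (!file.exists(f)) ca_stop("missing image file '%s'", f)
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    img
  })
  names(out) <- cohort$image_id
  out
}
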