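#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Column layout shared across the package. Translations are millimetres,
# rotations degrees; the axis convention is the patient/couch system:
# lateral = x, longitudinal (superior-inferior) = y, vertical
# (anterior-posterior) = z; pitch about x, roll about y, yaw about z.
trans_axes <- c("lat_mm", "long_mm", "vert_mm")
rot_axes <- c("pitch_deg", "roll_deg", "yaw_deg")
shift_axes <- c(trans_axes, rot_axes)
setup_columns <- c("patient_id", "treatment_id", "fraction", "stage", shift_axes)
wl_columns <- c("date", "axis", trans_axes)
sag_columns <- c("load_kg", "angle_deg", trans_axes, "pitch_deg", "roll_deg")

wl_axis_levels <- c("gantry", "collimator", "couch_rotation", "kv_imager", "infrared")
stage_levels <- c("XC", "XV", "XV2")

#' Radial (quadrature) displacement magnitude
#'
#' Collapses the three translational components of a 6D shift into a single
#' displacement magnitude, the quadrature sum
#' \eqn{r = \sqrt{x^2 + y^2 + z^2}}. Rotations are never included. Missing
#' components contribute zero, mirroring how "n/a" cells are treated
#' throughout the package.
#'
#' @param lat_mm,long_mm,vert_mm Numeric vectors of translational shifts (mm),
#'   recycled to a common length.
#' @return A non-negative numeric vector of radial displacements (mm).
#' @examples
#' radial_shift(-0.20, 0.60, -0.30) # 0.70
#' radial_shift(3, 4, 0)            # 5
#' @export
radial_shift <- function(lat_mm, long_mm, vert_mm) {
  n <- max(length(lat_mm), length(long_mm), length(vert_mm))
  m <- cbind(rep_len(lat_mm, n), rep_len(long_mm, n), rep_len(vert_mm, n))
  if (any(is.infinite(m))) {
    stop("translational components must be finite", call. = FALSE)
  }
  m[is.na(m)] <- 0
  sqrt(rowSums(m^2))
}

#' Append a radial-displacement column to a shift table
#'
#' @param data A data frame with `lat_mm`, `long_mm`, `vert_mm` columns.
#' @return `data` as a tibble with a `radial_mm` column appended.
#' @export
add_radial <- function(data) {
  data <- as_tibble(data)
  data$radial_mm <- radial_shift(data$lat_mm, data$long_mm, data$vert_mm)
  data
}

#' Tolerance gate for 6D shifts
#'
#' Decides, per record, whether a 6D shift is inside the clinical action
#' tolerance: every translational component within `trans_tol` and every
#' rotational component within `rot_tol`, boundaries inclusive (a setup
#' exactly at tolerance is treated). Defaults are the institutional criteria
#' of 0.7 mm and 1 degree.
#'
#' @param data A data frame carrying the six shift columns (`lat_mm`,
#'   `long_mm`, `vert_mm`, `pitch_deg`, `roll_deg`, `yaw_deg`).
#' @param trans_tol Translational tolerance in mm (> 0).
#' @param rot_tol Rotational tolerance in degrees (> 0).
#' @return A logical vector, one element per row of `data`.
#' @export
within_tolerance <- function(data, trans_tol = 0.7, rot_tol = 1.0) {
  stopifnot(is.numeric(trans_tol), trans_tol > 0, is.numeric(rot_tol), rot_tol > 0)
  m <- as.matrix(as.data.frame(data)[, shift_axes, drop = FALSE])
  if (any(!is.finite(m))) {
    stop("shift components must be finite for tolerance checks", call. = FALSE)
  }
  trans_ok <- rowSums(abs(m[, trans_axes, drop = FALSE]) > trans_tol) == 0
  rot_ok <- rowSums(abs(m[, rot_axes, drop = FALSE]) > rot_tol) == 0
  unname(trans_ok & rot_ok)
}

fail_rows <- function(what, rows) {
  stop(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
               paste(utils::head(rows, 5L), collapse = ", ")), call. = FALSE)
}

#' Validate a table of setup records
#'
#' Checks the contract every setup-shift table must satisfy: all nine columns
#' present, shifts finite, stages among XC/XV/XV2, `(treatment_id, fraction,
#' stage)` unique, and an XV2 only where an XV exists for the same fraction.
#' Row numbers in error messages refer to data rows (header excluded).
#'
#' @param data A data frame of setup records.
#' @return The validated data as a tibble, invisibly usable in pipes.
#' @export
validate_setup_records <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(setup_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) {
    return(data[, setup_columns])
  }
  for (ax in shift_axes) {
    if (!is.numeric(data[[ax]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[ax]]))))
      fail_rows(sprintf("non-numeric value in column '%s'", ax),
                if (length(bad)) bad else seq_len(nrow(data)))
    }
    if (any(!is.finite(data[[ax]]))) {
      fail_rows(sprintf("non-finite value in column '%s'", ax),
                which(!is.finite(data[[ax]])))
    }
  }
  if (!is.numeric(data$fraction) || any(data$fraction < 1) ||
      any(data$fraction != round(data$fraction))) {
    fail_rows("fraction must be a positive integer",
              which(!is.finite(data$fraction) | data$fraction < 1 |
                      data$fraction != round(data$fraction)))
  }
  if (any(!data$stage %in% stage_levels)) {
    fail_rows(sprintf("stage must be one of %s", paste(stage_levels, collapse = "/")),
              which(!data$stage %in% stage_levels))
  }
  key <- paste(data$treatment_id, data$fraction, data$stage, sep = "\r")
  if (anyDuplicated(key)) {
    fail_rows("duplicate (treatment_id, fraction, stage)", which(duplicated(key)))
  }
  xv2 <- data$stage == "XV2"
  if (any(xv2)) {
    has_xv <- paste(data$treatment_id, data$fraction)[data$stage == "XV"]
    orphan <- xv2 & !paste(data$treatment_id, data$fraction) %in% has_xv
    if (any(orphan)) fail_rows("XV2 record without a matching XV", which(orphan))
  }
  data[, setup_columns]
}

read_delim_quiet <- function(path, delim, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_delim(path, delim = delim, col_types = col_types,
                    na = c("", "NA", "n/a", "N/A"), progress = FALSE,
                    show_col_types = FALSE)
}

#' Read a setup-shift table
#'
#' Reads the per-fraction couch-shift table (one row per imaging event) from
#' delimited text and validates it. The expected header is
#' `patient_id,treatment_id,fraction,stage,lat_mm,long_mm,vert_mm,pitch_deg,roll_deg,yaw_deg`.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @return A validated tibble of setup records, row order preserved.
#' @export
read_setup_table <- function(path, delim = ",") {
  raw <- read_delim_quiet(path, delim, readr::cols(
    patient_id = readr::col_character(), treatment_id = readr::col_character(),
    fraction = readr::col_double(), stage = readr::col_character(),
    .default = readr::col_character()))
  missing_cols <- setdiff(setup_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (ax in shift_axes) {
    parsed <- suppressWarnings(as.numeric(raw[[ax]]))
    bad <- which(is.na(parsed) & !is.na(raw[[ax]]))
    if (length(bad) > 0) fail_rows(sprintf("non-numeric value in column '%s'", ax), bad)
    if (anyNA(parsed)) fail_rows(sprintf("missing value in column '%s'", ax), which(is.na(parsed)))
    raw[[ax]] <- parsed
  }
  validate_setup_records(raw)
}

#' Write a setup-shift table
#'
#' @param data A data frame of setup records (validated before writing).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_setup_table <- function(data, path, delim = ",") {
  data <- validate_setup_records(data)
  readr::write_delim(data, path, delim = delim, na = "n/a")
  invisible(path)
}

#' Read a Winston-Lutz QA log
#'
#' One row per monthly QA measurement: `date,axis,lat_mm,long_mm,vert_mm`,
#' where `axis` names the rotation axis under test (gantry, collimator,
#' couch_rotation, kv_imager, infrared). Vertical offsets are not measurable
#' for collimator and couch rotation and appear as `n/a`; they are kept as
#' explicit missing values, never silently zero-filled.
#'
#' @inheritParams read_setup_table
#' @return A tibble of isocenter-offset records.
#' @export
read_wl_log <- function(path, delim = ",") {
  raw <- read_delim_quiet(path, delim, readr::cols(
    date = readr::col_character(), axis = readr::col_character(),
    .default = readr::col_double()))
  missing_cols <- setdiff(wl_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!raw$axis %in% wl_axis_levels)) {
    fail_rows(sprintf("axis must be one of %s", paste(wl_axis_levels, collapse = "/")),
              which(!raw$axis %in% wl_axis_levels))
  }
  raw[, wl_columns]
}

#' @rdname read_wl_log
#' @param data A data frame of isocenter-offset records.
#' @export
write_wl_log <- function(data, path, delim = ",") {
  readr::write_delim(as_tibble(data)[, wl_columns], path, delim = delim, na = "n/a")
  invisible(path)
}

#' Read a couch-sag phantom table
#'
#' One row per (load, couch angle) phantom measurement:
#' `load_kg,angle_deg,lat_mm,long_mm,vert_mm,pitch_deg,roll_deg`. Yaw is not
#' resolvable in the phantom study and is not a column; downstream arithmetic
#' treats it as absent.
#'
#' @inheritParams read_setup_table
#' @return A tibble of couch-sag records.
#' @export
read_couch_sag <- function(path, delim = ",") {
  raw <- read_delim_quiet(path, delim, readr::cols(.default = readr::col_double()))
  missing_cols <- setdiff(sag_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(raw$load_kg) & raw$load_kg < 0)) {
    fail_rows("load_kg must be non-negative", which(raw$load_kg < 0))
  }
  if (any(raw$angle_deg < 0 | raw$angle_deg >= 360)) {
    fail_rows("angle_deg must lie in [0, 360)", which(raw$angle_deg < 0 | raw$angle_deg >= 360))
  }
  raw[, sag_columns]
}

#' @rdname read_couch_sag
#' @param data A data frame of couch-sag records.
#' @export
write_couch_sag <- function(data, path, delim = ",") {
  readr::write_delim(as_tibble(data)[, sag_columns], path, delim = delim, na = "n/a")
  invisible(path)
}
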