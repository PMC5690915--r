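#' Reference couch-sag phantom table
#'
#' The load-by-angle couch-sag grid used as the default phantom study for the
#' synthetic cohort: weights of 0, 10, 50 and 70 kg at couch angles 0, 45,
#' 90, 270 and 315 degrees (the 90 and 270 degree rows are measured at 70 kg
#' only), with per-axis sag in mm and pitch/roll in degrees. Yaw is not
#' resolvable in this phantom setup and is absent by design. Sag is a
#' deterministic property of the couch, so this table is reused verbatim by
#' [generate_couch_sag()].
#'
#' @return A tibble with columns `load_kg`, `angle_deg`, `lat_mm`, `long_mm`,
#'   `vert_mm`, `pitch_deg`, `roll_deg`.
#' @export
couch_sag_reference <- function() {
  tibble::tribble(
    ~load_kg, ~angle_deg, ~lat_mm, ~long_mm, ~vert_mm, ~pitch_deg, ~roll_deg,
    0,   0,    0.01,  0.01,  0.01,  0.30, -0.10,
    0,   45,  -0.20,  0.60, -0.30,  0.40, -0.10,
    0,   315,  0.20,  0.04, -0.75,  0.10,  0.10,
    10,  0,    0.01,  0.01,  0.01,  0.20, -0.10,
    10,  45,   0.00,  0.60, -0.30,  0.30, -0.10,
    10,  315,  0.30,  0.07, -0.78,  0.00,  0.10,
    50,  0,    0.01,  0.01,  0.01,  0.20, -0.10,
    50,  45,   0.25,  0.50, -0.30,  0.30, -0.10,
    50,  315,  0.48,  0.08, -0.78,  0.00,  0.10,
    70,  0,    0.01,  0.01,  0.01,  0.10, -0.10,
    70,  45,   0.01,  0.64, -0.20,  0.30, -0.10,
    70,  90,  -0.25,  0.37, -0.10,  0.00,  0.10,
    70,  270,  0.40, -0.97, -0.29,  0.30,  0.00,
    70,  315,  0.85,  0.01, -0.68, -0.10,  0.20
  )
}

#' Reference Winston-Lutz axis parameters
#'
#' Per rotation axis (gantry, collimator, couch rotation for the MV machine;
#' kV imager gantry; infrared system), the mean and spread of the
#' translational isocenter offset used to generate monthly QA logs. Vertical
#' offsets are not measurable for the collimator and couch-rotation tests and
#' are `NA`.
#'
#' @return A tibble with columns `axis`, `mean_lat`, `mean_long`, `mean_vert`,
#'   `sd_lat`, `sd_long`, `sd_vert`.
#' @export
wl_axis_reference <- function() {
  tibble::tribble(
    ~axis,            ~mean_lat, ~mean_long, ~mean_vert, ~sd_lat, ~sd_long, ~sd_vert,
    "gantry",          0.27,      0.24,       0.34,       0.27,    0.24,     0.34,
    "collimator",      0.32,      0.24,       NA,         0.21,    0.14,     NA,
    "couch_rotation",  0.32,      0.22,       NA,         0.21,    0.13,     NA,
    "kv_imager",       0.15,     -0.40,       0.21,       0.80,    0.16,     0.09,
    "infrared",        0.02,      0.02,       0.02,       0.01,    0.01,     0.01
  )
}

default_fraction_schedule <- function(n_treatments = 49) {
  # 49 treatments in 1/3/5 fractions totalling 203 XC setups: 4x1 + 13x3 + 32x5.
  base <- c(rep(1L, 4L), rep(3L, 13L), rep(5L, 32L))
  rep_len(base, n_treatments)
}

six <- function(x, what) {
  stopifnot(is.numeric(x), length(x) == 6, all(is.finite(x)))
  stats::setNames(as.numeric(x), shift_axes)
}

#' Ground truth for a synthetic setup cohort
#'
#' Bundles every generative parameter of the synthetic cohort, so that
#' estimator tests can compare recovered components against known truth. The
#' generative model mirrors the clinical workflow: each treatment course
#' carries a static per-mask bias drawn from a zero-mean normal with spread
#' `mask_sd`; each fraction's pre-correction (XC) shift is
#' mask bias + infrared-frame systematic + per-fraction repositioning noise
#' (`setup_sd`) + X-ray registration noise (`xray_sd`); whenever the XC shift
#' exceeds the action tolerance the couch is corrected and a verification
#' (XV) image is taken, whose residual shift is the stereotactic-localizer
#' systematic plus fresh registration noise.
#'
#' Defaults reproduce the study conditions this package models: 49 treatment
#' courses over 35 patients in 1, 3 or 5 fractions (203 XC setups), frame and
#' localizer systematics and per-fraction spreads at the magnitudes typical
#' of frameless cranial 6D image guidance, monthly Winston-Lutz logs, and the
#' [couch_sag_reference()] phantom grid.
#'
#' @param n_treatments Number of treatment courses.
#' @param fractions_per_treatment Integer vector (values in 1/3/5), one entry
#'   per treatment.
#' @param n_patients Number of patients the courses are spread over.
#' @param frame_systematic,localizer_systematic Length-6 numeric vectors
#'   (lat, long, vert in mm; pitch, roll, yaw in degrees).
#' @param mask_sd,setup_sd,xray_sd Length-6 non-negative spreads on the same
#'   axes: cross-patient mask-bias spread, per-fraction repositioning spread,
#'   and X-ray registration spread.
#' @param wl_axes Winston-Lutz axis parameter table, see [wl_axis_reference()].
#' @param couch_sag_table Couch-sag phantom grid, see [couch_sag_reference()].
#' @param trans_tol,rot_tol Action tolerances gating XV acquisition.
#' @param force_xv If `TRUE`, an XV record is emitted for every fraction
#'   regardless of tolerance (useful for estimator unit tests).
#' @param mask_tail_df Degrees of freedom of a Student-t tail for mask biases;
#'   `Inf` (default) keeps them normal. A finite value emulates the occasional
#'   shrunk or loosened mask producing outlying biases.
#' @param seed Integer seed; the generator is fully determined by it.
#' @return An object of class `cohort_truth` (a list).
#' @export
cohort_truth <- function(n_treatments = 49L,
                         fractions_per_treatment = default_fraction_schedule(n_treatments),
                         n_patients = 35L,
                         frame_systematic = c(0.18, 0.25, -1.27, -0.32, 0.18, 0.47),
                         localizer_systematic = c(-0.03, -0.01, 0.03, -0.03, 0.00, -0.01),
                         mask_sd = c(0.73, 2.05, 1.37, 0.51, 0.72, 0.87),
                         setup_sd = c(0.42, 0.46, 0.20, 0.30, 0.33, 0.32),
                         xray_sd = c(0.25, 0.26, 0.21, 0.25, 0.24, 0.24),
                         wl_axes = wl_axis_reference(),
                         couch_sag_table = couch_sag_reference(),
                         trans_tol = 0.7, rot_tol = 1.0,
                         force_xv = FALSE, mask_tail_df = Inf,
                         seed = 1L) {
  stopifnot(n_treatments >= 1, length(fractions_per_treatment) == n_treatments,
            all(fractions_per_treatment %in% c(1L, 3L, 5L)),
            n_patients >= 1, n_patients <= n_treatments,
            trans_tol > 0, rot_tol > 0, is.finite(seed))
  mask_sd <- six(mask_sd); setup_sd <- six(setup_sd); xray_sd <- six(xray_sd)
  stopifnot(all(mask_sd >= 0), all(setup_sd >= 0), all(xray_sd >= 0))
  structure(list(
    n_treatments = as.integer(n_treatments),
    fractions_per_treatment = as.integer(fractions_per_treatment),
    n_patients = as.integer(n_patients),
    frame_systematic = six(frame_systematic),
    localizer_systematic = six(localizer_systematic),
    mask_sd = mask_sd, setup_sd = setup_sd, xray_sd = xray_sd,
    wl_axes = tibble::as_tibble(wl_axes),
    couch_sag_table = tibble::as_tibble(couch_sag_table),
    trans_tol = trans_tol, rot_tol = rot_tol,
    force_xv = isTRUE(force_xv), mask_tail_df = mask_tail_df,
    seed = as.integer(seed)
  ), class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("<cohort_truth>", x$n_treatments, "treatments /", x$n_patients, "patients,",
      sum(x$fractions_per_treatment), "fractions, seed", x$seed, "\n")
  invisible(x)
}

rnorm6 <- function(n, mean = rep(0, 6), sd = rep(0, 6)) {
  m <- matrix(stats::rnorm(6L * n), nrow = n)
  m <- sweep(m, 2L, sd, `*`)
  sweep(m, 2L, mean, `+`)
}

#' Generate a synthetic setup cohort
#'
#' Draws a full cohort of per-fraction XC/XV setup records from the
#' generative model encoded in a [cohort_truth()], together with the
#' per-treatment true mask biases, so that estimators can be checked by
#' parameter recovery. The same truth (including its seed) always yields an
#' identical cohort.
#'
#' @param truth A [cohort_truth()].
#' @return A list with elements `records` (a validated setup-record tibble;
#'   XC rows for every fraction, XV rows only where the XC shift failed the
#'   tolerance gate, unless `truth$force_xv`) and `mask_bias` (a tibble of
#'   per-treatment true mask biases on the six axes).
#' @export
generate_cohort <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  withr::local_seed(truth$seed)
  nt <- truth$n_treatments
  treatment_id <- sprintf("T%02d", seq_len(nt))
  # spread courses over patients: first patients take the extra courses
  patient_of <- sort(rep_len(seq_len(truth$n_patients), nt))
  patient_id <- sprintf("P%02d", patient_of)

  if (is.finite(truth$mask_tail_df)) {
    tdf <- truth$mask_tail_df
    scale <- if (tdf > 2) sqrt((tdf - 2) / tdf) else 1
    mb <- matrix(stats::rt(6L * nt, df = tdf) * scale, nrow = nt)
    mb <- sweep(mb, 2L, truth$mask_sd, `*`)
  } else {
    mb <- rnorm6(nt, sd = truth$mask_sd)
  }
  colnames(mb) <- shift_axes
  mask_bias <- tibble(treatment_id = treatment_id, as_tibble(mb))

  rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    nf <- truth$fractions_per_treatment[t]
    xc <- sweep(rnorm6(nf, sd = truth$setup_sd) + rnorm6(nf, sd = truth$xray_sd),
                2L, mb[t, ] + truth$frame_systematic, `+`)
    colnames(xc) <- shift_axes
    xc_tb <- tibble(patient_id = patient_id[t], treatment_id = treatment_id[t],
                    fraction = seq_len(nf), stage = "XC", as_tibble(xc))
    need_xv <- truth$force_xv | !within_tolerance(xc_tb, truth$trans_tol, truth$rot_tol)
    out <- xc_tb
    if (any(need_xv)) {
      nxv <- sum(need_xv)
      xv <- sweep(rnorm6(nxv, sd = truth$xray_sd), 2L, truth$localizer_systematic, `+`)
      colnames(xv) <- shift_axes
      xv_tb <- tibble(patient_id = patient_id[t], treatment_id = treatment_id[t],
                      fraction = which(need_xv), stage = "XV", as_tibble(xv))
      out <- dplyr::bind_rows(xc_tb, xv_tb)
    }
    rows[[t]] <- out
  }
  records <- dplyr::arrange(dplyr::bind_rows(rows),
                            .data$treatment_id, .data$fraction, .data$stage)
  list(records = validate_setup_records(records), mask_bias = mask_bias)
}

#' Generate a synthetic Winston-Lutz QA log
#'
#' Draws `n_sessions` monthly QA sessions; in each, every rotation axis in
#' `truth$wl_axes` yields one translational offset record, per-axis normal
#' around that axis's mean offset with its spread. Components flagged `NA` in
#' the parameter table (vertical for collimator and couch rotation) stay
#' absent in the output.
#'
#' @param truth A [cohort_truth()].
#' @param n_sessions Number of QA sessions (>= 1).
#' @param seed Optional seed override; defaults to `truth$seed + 1` so the
#'   log is independent of the cohort draw yet still reproducible.
#' @return A tibble of isocenter-offset records (`date`, `axis`, `lat_mm`,
#'   `long_mm`, `vert_mm`).
#' @export
generate_wl_log <- function(truth, n_sessions = 24L, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (!is.numeric(n_sessions) || n_sessions < 1) {
    stop("n_sessions must be >= 1", call. = FALSE)
  }
  n_sessions <- as.integer(n_sessions)
  withr::local_seed(seed)
  ax <- truth$wl_axes
  out <- purrr::map_dfr(seq_len(nrow(ax)), function(i) {
    mu <- c(ax$mean_lat[i], ax$mean_long[i], ax$mean_vert[i])
    sd <- c(ax$sd_lat[i], ax$sd_long[i], ax$sd_vert[i])
    m <- matrix(stats::rnorm(3L * n_sessions), nrow = n_sessions)
    m <- sweep(m, 2L, ifelse(is.na(sd), 0, sd), `*`)
    m <- sweep(m, 2L, ifelse(is.na(mu), 0, mu), `+`)
    m[, is.na(mu) | is.na(sd)] <- NA_real_
    colnames(m) <- trans_axes
    tibble(date = sprintf("session-%03d", seq_len(n_sessions)),
           axis = ax$axis[i], as_tibble(m))
  })
  dplyr::arrange(out, .data$date, .data$axis)
}

#' Emit the couch-sag phantom table of a cohort truth
#'
#' Couch sag is a deterministic property of couch angle and load, so the
#' phantom study is a lookup rather than a random process: this returns the
#' configured grid verbatim.
#'
#' @param truth A [cohort_truth()].
#' @return A tibble of couch-sag records.
#' @export
generate_couch_sag <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  truth$couch_sag_table
}
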