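# Estimator mapping from record streams to named uncertainty components.
#
# Component naming follows the field's budget vocabulary: systematic (Sigma)
# components are means of shift distributions — reproducible biases tied to a
# hardware/software element — and random (sigma) components are standard
# deviations — session-to-session scatter. Sample SDs use denominator n - 1;
# a single observation contributes SD 0 by convention.

component_names <- c("mask", "setup", "frame", "localizer", "xray",
                     "couch_sag", "iso_mv", "iso_kv", "iso_ir")

# names of components removed by the X-ray correction step: the couch move
# driven by XC registration removes the patient's placement error inside the
# mask (mask bias + per-fraction setup scatter); everything downstream of the
# imaging chain survives it.
corrected_components <- c("mask", "setup")

component_row <- function(name, utype, values, radial, n) {
  v <- rep(NA_real_, 6)
  names(v) <- shift_axes
  v[names(values)] <- values
  tibble(name = name, utype = utype,
         lat_mm = v[["lat_mm"]], long_mm = v[["long_mm"]], vert_mm = v[["vert_mm"]],
         pitch_deg = v[["pitch_deg"]], roll_deg = v[["roll_deg"]], yaw_deg = v[["yaw_deg"]],
         radial_mm = radial, n = as.integer(n),
         corrected_by_xray = name %in% corrected_components)
}

sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Per-treatment mask and setup statistics from XC records
#'
#' For each treatment course, the mean of its pre-correction (XC) shifts on
#' every axis estimates the mask systematic bias for that course, and the
#' sample SD estimates the per-fraction setup (repositioning) random
#' uncertainty. A single-fraction course contributes its one shift as the
#' mean and an SD of exactly zero. The radial summary of the mask component
#' is the mean of the per-fraction radial displacements (not the quadrature
#' of per-axis means), and the setup radial is the SD of those radials.
#'
#' @param records A setup-record tibble; only `stage == "XC"` rows are used.
#' @param group Grouping key: `"treatment_id"` (default, one series per
#'   isocenter) or `"patient_id"`.
#' @return A tibble with one row per group: `n_fractions`, six `mask_*`
#'   columns plus `mask_radial_mm`, six `setup_*` columns plus
#'   `setup_radial_mm`.
#' @export
per_treatment_stats <- function(records, group = c("treatment_id", "patient_id")) {
  group <- match.arg(group)
  xc <- dplyr::filter(as_tibble(records), .data$stage == "XC")
  if (nrow(xc) == 0) stop("no XC records to summarize", call. = FALSE)
  xc <- add_radial(xc)
  out <- xc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n_fractions = dplyr::n(),
      dplyr::across(dplyr::all_of(shift_axes),
                    list(mean = mean, sd = sd0)),
      mask_radial_mm = mean(.data$radial_mm),
      setup_radial_mm = sd0(.data$radial_mm),
      .groups = "drop")
  nm <- names(out)
  nm <- sub("^(lat_mm|long_mm|vert_mm|pitch_deg|roll_deg|yaw_deg)_mean$", "mask_\\1", nm)
  nm <- sub("^(lat_mm|long_mm|vert_mm|pitch_deg|roll_deg|yaw_deg)_sd$", "setup_\\1", nm)
  names(out) <- nm
  out
}

#' Infrared-frame systematic component from all XC records
#'
#' The per-axis mean over every XC setup in the cohort (pooled over fractions
#' and treatments) estimates the systematic bias of the infrared positioning
#' frame: with mask biases averaging out across the cohort, what remains in
#' the grand mean is the frame's reproducible offset. The radial summary is
#' the mean of per-record radial displacements.
#'
#' @param records A setup-record tibble; only XC rows are used (>= 2 needed).
#' @return A one-row component tibble.
#' @export
frame_systematic <- function(records) {
  xc <- dplyr::filter(as_tibble(records), .data$stage == "XC")
  if (nrow(xc) < 2) stop("need at least 2 XC records", call. = FALSE)
  xc <- add_radial(xc)
  m <- colMeans(as.matrix(xc[, shift_axes]))
  component_row("frame", "systematic", m, mean(xc$radial_mm), nrow(xc))
}

#' Localizer systematic and X-ray registration random components
#'
#' The verification (XV) images are taken after the couch correction, so the
#' patient-dependent errors are gone: the mean of all XV residual shifts
#' estimates the systematic bias of the stereotactic localization chain
#' (localizer + planning), and their spread estimates the random uncertainty
#' of X-ray image quality and registration. The spread is, canonically, the
#' pooled SD of all XV shifts; `sd_method = "of_means"` instead takes the SD
#' of per-treatment XV means (an alternative reading of the estimator table,
#' retained for comparison).
#'
#' @param records A setup-record tibble; `stage %in% c("XV", "XV2")` rows with
#'   stage `"XV"` are used (>= 2 needed).
#' @param sd_method `"pooled"` (default) or `"of_means"`.
#' @param group Grouping key used by `"of_means"`.
#' @return A two-row component tibble: `localizer` (systematic) and `xray`
#'   (random).
#' @export
localizer_and_xray <- function(records, sd_method = c("pooled", "of_means"),
                               group = c("treatment_id", "patient_id")) {
  sd_method <- match.arg(sd_method)
  group <- match.arg(group)
  xv <- dplyr::filter(as_tibble(records), .data$stage == "XV")
  if (nrow(xv) < 2) stop("need at least 2 XV records", call. = FALSE)
  xv <- add_radial(xv)
  m <- colMeans(as.matrix(xv[, shift_axes]))
  loc <- component_row("localizer", "systematic", m, mean(xv$radial_mm), nrow(xv))
  if (sd_method == "pooled") {
    s <- apply(as.matrix(xv[, shift_axes]), 2L, stats::sd)
    sr <- stats::sd(xv$radial_mm)
    n <- nrow(xv)
  } else {
    means <- xv |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(c(shift_axes, "radial_mm")), mean),
                       .groups = "drop")
    s <- apply(as.matrix(means[, shift_axes]), 2L, sd0)
    sr <- sd0(means$radial_mm)
    n <- nrow(means)
  }
  dplyr::bind_rows(loc, component_row("xray", "random", s, sr, n))
}

#' Axis summary with one-sample t-test
#'
#' Summarizes one axis of a shift distribution the way setup-error tables
#' report it: mean, sample SD, extreme values, and the two-sided one-sample
#' t-test p-value for the mean differing from zero (p >= 0.05 read as no
#' statistically significant bias). Degenerate inputs are flagged rather
#' than silently propagated: with fewer than two values SD and p are absent;
#' with zero SD the t statistic is undefined, so p is absent for a zero mean
#' and reported as 0 (below any machine floor) for a nonzero mean.
#'
#' @param values Numeric vector of signed shifts on one axis.
#' @return A one-row tibble: `n`, `mean`, `sd`, `p_value`, `min`, `max`,
#'   `degenerate` (TRUE when the t-test could not be computed normally).
#' @export
axis_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) {
    return(tibble(n = 0L, mean = NA_real_, sd = NA_real_, p_value = NA_real_,
                  min = NA_real_, max = NA_real_, degenerate = TRUE))
  }
  m <- mean(values)
  if (n < 2) {
    return(tibble(n = 1L, mean = m, sd = NA_real_, p_value = NA_real_,
                  min = m, max = m, degenerate = TRUE))
  }
  s <- stats::sd(values)
  if (s == 0) {
    p <- if (m == 0) NA_real_ else 0
    return(tibble(n = n, mean = m, sd = 0, p_value = p,
                  min = min(values), max = max(values), degenerate = TRUE))
  }
  p <- stats::t.test(values, mu = 0)$p.value
  tibble(n = n, mean = m, sd = s, p_value = p,
         min = min(values), max = max(values), degenerate = FALSE)
}

#' Cohort shift summary table
#'
#' The per-axis summary (mean, SD, p, min, max) of a record stream for one
#' stage, plus the same summary of the radial displacement (without a
#' p-value: the radial is non-negative by construction, so a mean-zero test
#' is meaningless).
#'
#' @param records A setup-record tibble.
#' @param stage Which stage to summarize (`"XC"` or `"XV"`).
#' @return A tibble with one row per axis and one `radial_mm` row.
#' @export
summarize_shifts <- function(records, stage = c("XC", "XV")) {
  stage <- match.arg(stage)
  sub <- dplyr::filter(as_tibble(records), .data$stage == !!stage)
  if (nrow(sub) == 0) stop("no ", stage, " records to summarize", call. = FALSE)
  sub <- add_radial(sub)
  out <- purrr::map_dfr(c(shift_axes, "radial_mm"), function(ax) {
    s <- axis_summary(sub[[ax]])
    dplyr::bind_cols(tibble(axis = ax), s)
  })
  out$p_value[out$axis == "radial_mm"] <- NA_real_
  out$stage <- stage
  out
}

#' Isocentricity components from a Winston-Lutz QA log
#'
#' Computes per rotation axis the mean and SD of the translational isocenter
#' offsets, then composes the MV-machine isocentricity systematic as the
#' per-axis sum of the gantry, collimator and couch-rotation means (the three
#' mobile components whose rotation isocenters can each miss the radiation
#' isocenter); offsets that are unmeasurable for an axis (`NA`) contribute
#' zero to the sum. The kV-imager and infrared components are the respective
#' means taken directly. Random counterparts (SDs, combined in quadrature for
#' the MV composition) are returned alongside.
#'
#' @param records A tibble of isocenter-offset records (see [read_wl_log()]).
#' @return A list: `components`, a component tibble with rows `iso_mv`,
#'   `iso_kv`, `iso_ir` (systematic) and their random counterparts
#'   where available; `by_axis`, the per-rotation-axis mean/SD table.
#' @export
winston_lutz_components <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) stop("empty Winston-Lutz log", call. = FALSE)
  by_axis <- records |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(trans_axes),
                    list(mean = ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE),
                         sd = ~ if (all(is.na(.x))) NA_real_ else sd0(.x[!is.na(.x)]))),
      .groups = "drop")
  get <- function(axis, stat) {
    row <- by_axis[by_axis$axis == axis, ]
    if (nrow(row) == 0) return(NULL)
    v <- unlist(row[paste0(trans_axes, "_", stat)])
    stats::setNames(as.numeric(v), trans_axes)
  }
  zero_na <- function(v) ifelse(is.na(v), 0, v)
  comp <- list()
  mv_parts <- list(get("gantry", "mean"), get("collimator", "mean"),
                   get("couch_rotation", "mean"))
  have_mv <- !vapply(mv_parts, is.null, logical(1))
  if (any(have_mv)) {
    mv <- Reduce(`+`, lapply(mv_parts[have_mv], zero_na))
    n_mv <- sum(by_axis$n[by_axis$axis %in% c("gantry", "collimator", "couch_rotation")])
    comp$iso_mv <- component_row("iso_mv", "systematic", mv,
                                 radial_shift(mv[1], mv[2], mv[3]), n_mv)
    mv_sd_parts <- list(get("gantry", "sd"), get("collimator", "sd"),
                        get("couch_rotation", "sd"))
    mv_sd <- sqrt(Reduce(`+`, lapply(mv_sd_parts[have_mv], function(v) zero_na(v)^2)))
    comp$iso_mv_sd <- component_row("iso_mv", "random", mv_sd,
                                    radial_shift(mv_sd[1], mv_sd[2], mv_sd[3]), n_mv)
  }
  for (ax in c(kv_imager = "iso_kv", infrared = "iso_ir")) {
    src <- names(which(c(kv_imager = "iso_kv", infrared = "iso_ir") == ax))
    m <- get(src, "mean")
    if (is.null(m)) next
    n_ax <- by_axis$n[by_axis$axis == src]
    comp[[ax]] <- component_row(ax, "systematic", m,
                                radial_shift(m[1], m[2], m[3]), n_ax)
    s <- get(src, "sd")
    comp[[paste0(ax, "_sd")]] <- component_row(ax, "random", s,
                                               radial_shift(s[1], s[2], s[3]), n_ax)
  }
  missing <- setdiff(c("gantry", "kv_imager", "infrared"), by_axis$axis)
  if (length(missing) > 0) {
    warning("Winston-Lutz log has no records for: ", paste(missing, collapse = ", "),
            "; the corresponding component(s) are absent", call. = FALSE)
  }
  list(components = dplyr::bind_rows(comp), by_axis = by_axis)
}

#' Couch-sag systematic component from the phantom table
#'
#' Selects the budget entry for couch sag. The default `worst_case` policy
#' takes the phantom row with the largest radial sag — a conservative choice,
#' since the sag at blocked couch angles cannot be imaged away — breaking
#' radial ties toward larger load, then larger angle. `at_angle` picks a
#' specific (load, angle) cell instead.
#'
#' @param records A couch-sag tibble (see [read_couch_sag()]).
#' @param policy `"worst_case"` (default) or `"at_angle"`.
#' @param load,angle The cell to pick when `policy = "at_angle"`.
#' @return A one-row component tibble (name `couch_sag`, systematic); yaw is
#'   absent (`NA`) because the phantom cannot resolve it.
#' @export
couch_sag_component <- function(records, policy = c("worst_case", "at_angle"),
                                load = NULL, angle = NULL) {
  policy <- match.arg(policy)
  records <- as_tibble(records)
  if (nrow(records) == 0) stop("empty couch-sag table", call. = FALSE)
  records <- add_radial(records)
  if (policy == "worst_case") {
    pick <- records |>
      dplyr::arrange(dplyr::desc(.data$radial_mm), dplyr::desc(.data$load_kg),
                     dplyr::desc(.data$angle_deg)) |>
      dplyr::slice(1)
  } else {
    if (is.null(load) || is.null(angle)) {
      stop("policy 'at_angle' needs load and angle", call. = FALSE)
    }
    pick <- dplyr::filter(records, .data$load_kg == load, .data$angle_deg == angle)
    if (nrow(pick) == 0) stop("no couch-sag record at load ", load, " kg, angle ",
                              angle, " deg", call. = FALSE)
  }
  v <- c(lat_mm = pick$lat_mm, long_mm = pick$long_mm, vert_mm = pick$vert_mm,
         pitch_deg = pick$pitch_deg, roll_deg = pick$roll_deg)
  component_row("couch_sag", "systematic", v, pick$radial_mm, nrow(records))
}

#' Decompose record streams into a full component table
#'
#' Runs the whole estimator mapping: per-treatment mask/setup statistics and
#' their cohort-level summaries, the frame systematic, the localizer
#' systematic and X-ray registration random components, the Winston-Lutz
#' isocentricity components, and the couch-sag component. The cohort-level
#' mask row summarizes the per-treatment biases (per-axis SD across
#' treatments, radial = mean per-treatment radial bias); the setup row is the
#' across-treatment mean of the per-fraction SDs.
#'
#' @param setup_records A setup-record tibble (XC and XV rows).
#' @param wl_records A Winston-Lutz log tibble.
#' @param sag_records A couch-sag tibble.
#' @param group Grouping key for per-treatment statistics.
#' @param sd_method X-ray spread estimator, see [localizer_and_xray()].
#' @param sag_policy,sag_load,sag_angle Couch-sag selection, see
#'   [couch_sag_component()].
#' @return An object of class `uncertainty_components`: a list with
#'   `components` (one row per named component), `per_treatment`,
#'   `summaries` (XC and XV per-axis tables), `wl_by_axis`, and the options
#'   used.
#' @export
decompose_components <- function(setup_records, wl_records, sag_records,
                                 group = c("treatment_id", "patient_id"),
                                 sd_method = c("pooled", "of_means"),
                                 sag_policy = c("worst_case", "at_angle"),
                                 sag_load = NULL, sag_angle = NULL) {
  group <- match.arg(group)
  sd_method <- match.arg(sd_method)
  sag_policy <- match.arg(sag_policy)
  per_trt <- per_treatment_stats(setup_records, group = group)
  mask_sd_axes <- apply(as.matrix(per_trt[, paste0("mask_", shift_axes)]), 2L, sd0)
  names(mask_sd_axes) <- shift_axes
  mask_row <- component_row("mask", "systematic", mask_sd_axes,
                            mean(per_trt$mask_radial_mm), nrow(per_trt))
  setup_means <- colMeans(as.matrix(per_trt[, paste0("setup_", shift_axes)]))
  names(setup_means) <- shift_axes
  setup_row <- component_row("setup", "random", setup_means,
                             mean(per_trt$setup_radial_mm), nrow(per_trt))
  frame <- frame_systematic(setup_records)
  lx <- localizer_and_xray(setup_records, sd_method = sd_method, group = group)
  wl <- winston_lutz_components(wl_records)
  sag <- couch_sag_component(sag_records, policy = sag_policy,
                             load = sag_load, angle = sag_angle)
  components <- dplyr::bind_rows(
    mask_row, setup_row, frame, lx, sag,
    dplyr::filter(wl$components, .data$utype == "systematic"))
  components <- components[order(match(components$name, component_names)), ]
  summaries <- dplyr::bind_rows(
    summarize_shifts(setup_records, "XC"),
    summarize_shifts(setup_records, "XV"))
  structure(list(
    components = components,
    per_treatment = per_trt,
    summaries = summaries,
    wl_by_axis = wl$by_axis,
    wl_components = wl$components,
    options = list(group = group, sd_method = sd_method, sag_policy = sag_policy)
  ), class = "uncertainty_components")
}

#' @export
print.uncertainty_components <- function(x, ...) {
  cat("<uncertainty_components>", nrow(x$components), "components from",
      nrow(x$per_treatment), "treatment series\n")
  print(x$components, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an uncertainty-component decomposition
#'
#' @param x An `uncertainty_components` object.
#' @param ... Unused.
#' @return The component table, one row per named component.
#' @export
tidy.uncertainty_components <- function(x, ...) x$components

#' One-line summary of a decomposition
#'
#' @param x An `uncertainty_components` object.
#' @param ... Unused.
#' @return A one-row tibble with record and component counts.
#' @export
glance.uncertainty_components <- function(x, ...) {
  xc <- x$summaries[x$summaries$stage == "XC" & x$summaries$axis == "lat_mm", ]
  xv <- x$summaries[x$summaries$stage == "XV" & x$summaries$axis == "lat_mm", ]
  tibble(n_treatments = nrow(x$per_treatment),
         n_xc = xc$n, n_xv = xv$n,
         n_components = nrow(x$components))
}
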