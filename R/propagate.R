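# Combination rules for uncertainty budgets.
#
# Two conventions are implemented side by side. The package's model adds
# systematic magnitudes linearly and random spreads in quadrature, then sums
# the two parts; the GUM convention adds every component in quadrature and
# multiplies by a coverage factor k for the expanded uncertainty. Because the
# 1-norm dominates the 2-norm on non-negative inputs, the model value is
# never below the GUM value for the same budget.

#' Linear combination of systematic magnitudes
#'
#' @param x Numeric vector of systematic magnitudes (signed means are taken
#'   by absolute value: cancellation across independent devices is not
#'   physically justified). `NA` entries (absent axes) contribute zero.
#' @return The arithmetic sum, >= 0; 0 for an empty input.
#' @export
combine_linear <- function(x) {
  if (length(x) == 0) return(0)
  sum(abs(x), na.rm = TRUE)
}

#' Quadrature combination of random spreads
#'
#' @param x Numeric vector of non-negative spreads; `NA` entries contribute
#'   zero.
#' @return `sqrt(sum(x^2))`; 0 for an empty input.
#' @export
combine_quadrature <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("spreads must be non-negative", call. = FALSE)
  if (length(x) == 0) return(0)
  sqrt(sum(x^2, na.rm = TRUE))
}

#' Cumulative uncertainty of one budget
#'
#' Combines a budget — components labelled systematic or random, each reduced
#' to a single magnitude — under both conventions:
#' model `CU = sum(|systematics|) + sqrt(sum(randoms^2))` and
#' GUM `CU = sqrt(sum(all components^2))`, with expanded GUM `k * CU_GUM`.
#'
#' @param budget A data frame with columns `name`, `utype`
#'   (`"systematic"`/`"random"`) and `magnitude` (mm).
#' @param k Coverage factor for the expanded GUM uncertainty (default 2).
#' @return A one-row tibble: `systematic_sum`, `random_quadrature`,
#'   `cu_model`, `cu_gum`, `cu_gum_expanded`, `k`.
#' @export
cumulative_uncertainty <- function(budget, k = 2) {
  stopifnot(is.numeric(k), k > 0)
  budget <- as_tibble(budget)
  if (nrow(budget) == 0) {
    warning("empty budget: cumulative uncertainty is zero", call. = FALSE)
    return(tibble(systematic_sum = 0, random_quadrature = 0, cu_model = 0,
                  cu_gum = 0, cu_gum_expanded = 0, k = k))
  }
  stopifnot(all(budget$utype %in% c("systematic", "random")))
  if (anyDuplicated(budget$name)) stop("component names must be unique", call. = FALSE)
  sys <- abs(budget$magnitude[budget$utype == "systematic"])
  rnd <- budget$magnitude[budget$utype == "random"]
  s <- combine_linear(sys)
  r <- combine_quadrature(rnd)
  g <- combine_quadrature(abs(budget$magnitude))
  tibble(systematic_sum = s, random_quadrature = r, cu_model = s + r,
         cu_gum = g, cu_gum_expanded = k * g, k = k)
}

budget_from_components <- function(components, names_keep, column) {
  comp <- components[components$name %in% names_keep, ]
  tibble(name = comp$name, utype = comp$utype, magnitude = comp[[column]])
}

per_axis_cu <- function(components, k) {
  # combine per translational axis, then take the radial of the three
  # per-axis cumulative values
  per_ax <- vapply(trans_axes, function(ax) {
    b <- tibble(name = components$name, utype = components$utype,
                magnitude = components[[ax]])
    unlist(cumulative_uncertainty(b, k = k)[c("systematic_sum", "random_quadrature",
                                              "cu_model", "cu_gum")])
  }, numeric(4))
  radial <- sqrt(rowSums(per_ax^2))
  tibble(systematic_sum = radial[["systematic_sum"]],
         random_quadrature = radial[["random_quadrature"]],
         cu_model = radial[["cu_model"]], cu_gum = radial[["cu_gum"]],
         cu_gum_expanded = k * radial[["cu_gum"]], k = k)
}

#' Per-treatment cumulative setup uncertainty
#'
#' Builds, for every treatment course, the pre-correction (before-XC) budget
#' — that course's mask bias and setup scatter plus the cohort-level frame,
#' localizer, couch-sag and isocentricity components and the X-ray
#' registration spread — and one after-XC budget holding only the components
#' the X-ray correction cannot remove. The after-XC budget contains no
#' patient-specific term, so its cumulative uncertainty is identical for
#' every treatment; it is computed once and reported as the residual
#' uncertainty (and margin basis) of the workflow.
#'
#' @param decomposition An [decompose_components()] result.
#' @param basis `"radial"` (default): each component enters as its radial
#'   magnitude. `"per_axis"`: combine per translational axis first, then take
#'   the radial of the three per-axis cumulative values. Both are legitimate
#'   readings of a single-number budget; radial is canonical here.
#' @param after_components Names of the components surviving the X-ray
#'   correction step. Default: frame, localizer, couch sag, the three
#'   isocentricities, and the X-ray registration spread.
#' @param k Coverage factor.
#' @return An object of class `cumulative_result`: list with `per_treatment`
#'   (before-XC CU per course), `after` (one-row after-XC CU), `basis`, `k`,
#'   `after_components`.
#' @export
per_treatment_cu <- function(decomposition,
                             basis = c("radial", "per_axis"),
                             after_components = c("frame", "localizer", "couch_sag",
                                                  "iso_mv", "iso_kv", "iso_ir", "xray"),
                             k = 2) {
  stopifnot(inherits(decomposition, "uncertainty_components"))
  basis <- match.arg(basis)
  comp <- decomposition$components
  shared_names <- setdiff(comp$name, c("mask", "setup"))
  shared <- comp[comp$name %in% shared_names, ]
  per_trt <- decomposition$per_treatment
  group <- decomposition$options$group
  if (nrow(per_trt) == 0) stop("decomposition has no treatments", call. = FALSE)

  one_before <- function(i) {
    if (basis == "radial") {
      b <- dplyr::bind_rows(
        tibble(name = c("mask", "setup"), utype = c("systematic", "random"),
               magnitude = c(per_trt$mask_radial_mm[i], per_trt$setup_radial_mm[i])),
        tibble(name = shared$name, utype = shared$utype, magnitude = shared$radial_mm))
      cumulative_uncertainty(b, k = k)
    } else {
      rows <- dplyr::bind_rows(
        tibble(name = "mask", utype = "systematic",
               lat_mm = per_trt$mask_lat_mm[i], long_mm = per_trt$mask_long_mm[i],
               vert_mm = per_trt$mask_vert_mm[i]),
        tibble(name = "setup", utype = "random",
               lat_mm = per_trt$setup_lat_mm[i], long_mm = per_trt$setup_long_mm[i],
               vert_mm = per_trt$setup_vert_mm[i]),
        shared[, c("name", "utype", trans_axes)])
      per_axis_cu(rows, k = k)
    }
  }
  before <- purrr::map_dfr(seq_len(nrow(per_trt)), one_before)
  before <- dplyr::bind_cols(per_trt[, c(group, "n_fractions")], before)

  missing_after <- setdiff(after_components, comp$name)
  if (length(missing_after) > 0) {
    warning("after-XC components not present in decomposition: ",
            paste(missing_after, collapse = ", "), call. = FALSE)
  }
  after_comp <- comp[comp$name %in% after_components, ]
  after <- if (basis == "radial") {
    cumulative_uncertainty(
      tibble(name = after_comp$name, utype = after_comp$utype,
             magnitude = after_comp$radial_mm), k = k)
  } else {
    per_axis_cu(after_comp[, c("name", "utype", trans_axes)], k = k)
  }
  structure(list(per_treatment = before, after = after, basis = basis, k = k,
                 after_components = intersect(after_components, comp$name),
                 group = group),
            class = "cumulative_result")
}

#' @export
print.cumulative_result <- function(x, ...) {
  cat("<cumulative_result> basis:", x$basis, " k:", x$k, "\n")
  cat(sprintf("before XC (model): %.2f +/- %.2f mm over %d treatments\n",
              mean(x$per_treatment$cu_model), stats::sd(x$per_treatment$cu_model),
              nrow(x$per_treatment)))
  cat(sprintf("after  XC: model %.2f mm, GUM %.2f mm, GUM expanded (k=%g) %.2f mm\n",
              x$after$cu_model, x$after$cu_gum, x$k, x$after$cu_gum_expanded))
  invisible(x)
}

#' Tidy a cumulative-uncertainty result
#'
#' @param x A `cumulative_result`.
#' @param ... Unused.
#' @return The per-treatment before-XC table with `stage` column, plus one
#'   after-XC row.
#' @export
tidy.cumulative_result <- function(x, ...) {
  before <- dplyr::mutate(x$per_treatment, stage = "before_XC")
  after <- dplyr::mutate(x$after, stage = "after_XC")
  dplyr::bind_rows(before, after)
}

#' One-row summary of a cumulative-uncertainty result
#'
#' @param x A `cumulative_result`.
#' @param ... Unused.
#' @return A one-row tibble with before-XC mean/SD/range of the model CU,
#'   the after-XC model and GUM values, and the recommended PTV margin
#'   (after-XC model CU rounded to 0.1 mm).
#' @export
glance.cumulative_result <- function(x, ...) {
  tibble(
    n_treatments = nrow(x$per_treatment),
    cu_before_model_mean = mean(x$per_treatment$cu_model),
    cu_before_model_sd = stats::sd(x$per_treatment$cu_model),
    cu_before_model_min = min(x$per_treatment$cu_model),
    cu_before_model_max = max(x$per_treatment$cu_model),
    cu_before_gum_mean = mean(x$per_treatment$cu_gum),
    cu_after_model = x$after$cu_model,
    cu_after_gum = x$after$cu_gum,
    cu_after_gum_expanded = x$after$cu_gum_expanded,
    k = x$k, basis = x$basis,
    margin_mm = round(x$after$cu_model, 1)
  )
}
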