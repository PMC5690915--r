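# Tables, histograms and plain-text report rendering. All data outputs are
# pure functions of the pipeline results: no timestamps inside files, so
# re-running on the same inputs is byte-identical.

#' Fixed-width histogram with origin-anchored bins
#'
#' Bins values into half-open intervals `[lo, lo + width)` whose edges are
#' anchored at `origin` (default 0), the binning convention used for
#' shift-distribution figures. Counts always sum to the number of finite
#' input values.
#'
#' @param values Numeric vector.
#' @param bin_width Positive bin width.
#' @param origin Bin-edge anchor.
#' @return A tibble with `bin_lo`, `bin_hi`, `count`; zero rows for empty
#'   input. Empty interior bins are kept so the bins tile the data range.
#' @export
shift_histogram <- function(values, bin_width, origin = 0) {
  stopifnot(is.numeric(bin_width), bin_width > 0)
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    return(tibble(bin_lo = numeric(), bin_hi = numeric(), count = integer()))
  }
  idx <- floor((values - origin) / bin_width)
  rng <- seq(min(idx), max(idx))
  counts <- tabulate(idx - min(idx) + 1L, nbins = length(rng))
  tibble(bin_lo = origin + rng * bin_width,
         bin_hi = origin + (rng + 1) * bin_width,
         count = as.integer(counts))
}

fmt2 <- function(x) ifelse(is.na(x), "n/a", sprintf("%.2f", x))

#' Render pipeline outputs to files
#'
#' Writes the machine-readable tables (`components.csv`, `summaries.csv`,
#' `per_treatment.csv`, `budget.csv`, `budget_summary.csv`) at full precision
#' and a human-readable `report.txt` rounded to two decimals. Sections with
#' no data are rendered as "no data" rather than omitted. Optionally writes
#' histogram and cumulative-uncertainty figures as PNG.
#'
#' @param decomposition An [decompose_components()] result, or `NULL`.
#' @param cu A [per_treatment_cu()] result, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param plots If `TRUE`, also write PNG figures.
#' @return Invisibly, the character vector of files written.
#' @export
render_report <- function(decomposition = NULL, cu = NULL, out_dir, plots = FALSE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory ", out_dir, call. = FALSE)
  }
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, na = "n/a")
    written <<- c(written, path)
  }
  lines <- c("Setup-uncertainty report", "========================", "")
  if (!is.null(decomposition)) {
    emit(decomposition$components, "components.csv")
    emit(decomposition$summaries, "summaries.csv")
    emit(decomposition$per_treatment, "per_treatment.csv")
    lines <- c(lines, "Uncertainty components (mm / degrees)", "",
               utils::capture.output(as.data.frame(
                 dplyr::mutate(decomposition$components,
                               dplyr::across(dplyr::where(is.double), fmt2)))),
               "")
  } else {
    lines <- c(lines, "Uncertainty components: no data", "")
  }
  if (!is.null(cu)) {
    emit(tidy(cu), "budget.csv")
    emit(glance(cu), "budget_summary.csv")
    g <- glance(cu)
    lines <- c(lines,
               "Cumulative uncertainty (CU)", "",
               sprintf("  before XC, model: %s +/- %s mm (range %s-%s) over %d treatments",
                       fmt2(g$cu_before_model_mean), fmt2(g$cu_before_model_sd),
                       fmt2(g$cu_before_model_min), fmt2(g$cu_before_model_max),
                       g$n_treatments),
               sprintf("  before XC, GUM:   %s mm (mean)", fmt2(g$cu_before_gum_mean)),
               sprintf("  after  XC, model: %s mm", fmt2(g$cu_after_model)),
               sprintf("  after  XC, GUM:   %s mm (expanded, k=%g: %s mm)",
                       fmt2(g$cu_after_gum), g$k, fmt2(g$cu_after_gum_expanded)),
               sprintf("  recommended PTV margin: %.1f mm", g$margin_mm),
               "")
  } else {
    lines <- c(lines, "Cumulative uncertainty: no data", "")
  }
  report_path <- file.path(out_dir, "report.txt")
  writeLines(lines, report_path)
  written <- c(written, report_path)
  if (plots && !is.null(decomposition)) {
    p <- autoplot.uncertainty_components(decomposition)
    path <- file.path(out_dir, "shift_histograms.png")
    ggplot2::ggsave(path, p, width = 9, height = 6, dpi = 120)
    written <- c(written, path)
  }
  if (plots && !is.null(cu)) {
    p <- autoplot.cumulative_result(cu)
    path <- file.path(out_dir, "cu_chart.png")
    ggplot2::ggsave(path, p, width = 9, height = 4, dpi = 120)
    written <- c(written, path)
  }
  invisible(written)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram panel of setup-shift distributions
#'
#' One facet per axis and stage, the standard way shift distributions are
#' inspected for normality and bias.
#'
#' @param object An `uncertainty_components` object.
#' @param bin_width Bin width (mm / degrees).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uncertainty_components <- function(object, bin_width = 0.5, ...) {
  per <- object$per_treatment
  long <- tidyr::pivot_longer(per, dplyr::starts_with("mask_") &
                                !dplyr::ends_with("radial_mm"),
                              names_to = "axis", values_to = "value")
  long$axis <- sub("^mask_", "", long$axis)
  long$axis <- factor(long$axis, levels = shift_axes)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            fill = "steelblue", colour = "grey20") +
    ggplot2::facet_wrap(~axis, scales = "free_x") +
    ggplot2::labs(x = "per-treatment mean XC shift (mm / deg)", y = "treatments",
                  title = "Mask systematic bias per treatment course")
}

#' Per-treatment cumulative-uncertainty chart
#'
#' Bar chart of the before-XC cumulative uncertainty per treatment course
#' under the model and GUM conventions, with the (treatment-independent)
#' after-XC values as horizontal reference lines.
#'
#' @param object A `cumulative_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cumulative_result <- function(object, ...) {
  per <- object$per_treatment
  key <- names(per)[1]
  long <- tidyr::pivot_longer(per[, c(key, "cu_model", "cu_gum")],
                              c("cu_model", "cu_gum"),
                              names_to = "rule", values_to = "cu")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[key]], y = .data$cu, fill = .data$rule)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$after$cu_model, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$after$cu_gum, linetype = 3) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6)) +
    ggplot2::labs(x = NULL, y = "cumulative uncertainty (mm)",
                  title = "Before-XC cumulative uncertainty per treatment",
                  subtitle = "dashed: after-XC model; dotted: after-XC GUM")
}
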