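# Screening classification against the 30 mm threshold and cohort-level
# metrics and summary statistics.

#' Screening configuration
#'
#' Collects every tunable constant of the pipeline. Defaults follow the
#' screening methodology: 30 mm AAA threshold, 2.5 mm centerline resampling,
#' spline smooth factor 0.5; the remaining constants are package defaults
#' exposed for override.
#'
#' @param threshold_mm AAA diameter threshold, mm (strictly greater -> AAA).
#' @param resampling_step_mm centerline resampling step, mm.
#' @param smooth_factor centerline spline smoothing in \[0, 1\].
#' @param smoothing_radius_mm morphological smoothing ball radius, mm.
#' @param section_step_mm cross-section spacing (NULL = resampling step).
#' @param prune_length_mm skeleton limb pruning threshold, mm.
#' @param binarize_threshold probability binarization threshold.
#' @param arch_margin_mm crop margin below the arch transition, mm.
#' @param iliac_margin_mm crop margin kept below the iliac transition, mm.
#' @param renal_inset_mm sectioning starts this far below the renal plane,
#'   clearing the renal ostia, mm.
#' @param iliac_inset_mm sectioning stops this far above the iliac plane, mm.
#' @param surface_sigma_vox Gaussian pre-smoothing (voxels) for isosurfacing.
#' @param rounding decimal places for reported percentages.
#' @param keep_geometry retain meshes/centerlines in results.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(threshold_mm = 30, resampling_step_mm = 2.5,
                          smooth_factor = 0.5, smoothing_radius_mm = 1.5,
                          section_step_mm = NULL, prune_length_mm = 5,
                          binarize_threshold = 0.5, arch_margin_mm = 3,
                          iliac_margin_mm = 15, renal_inset_mm = 8,
                          iliac_inset_mm = 2.5, surface_sigma_vox = 1,
                          rounding = 0, keep_geometry = FALSE) {
  if (!is.finite(threshold_mm) || threshold_mm <= 0) stop("threshold_mm must be > 0")
  structure(list(threshold_mm = threshold_mm, resampling_step_mm = resampling_step_mm,
                 smooth_factor = smooth_factor, smoothing_radius_mm = smoothing_radius_mm,
                 section_step_mm = section_step_mm, prune_length_mm = prune_length_mm,
                 binarize_threshold = binarize_threshold, arch_margin_mm = arch_margin_mm,
                 iliac_margin_mm = iliac_margin_mm, renal_inset_mm = renal_inset_mm,
                 iliac_inset_mm = iliac_inset_mm, surface_sigma_vox = surface_sigma_vox,
                 rounding = rounding, keep_geometry = keep_geometry),
            class = "screen_config")
}

#' Classify a diameter as AAA or control
#'
#' AAA if and only if the diameter strictly exceeds the threshold (default
#' 30 mm); a diameter exactly at the threshold is a control.
#'
#' @param diameter_mm maximum abdominal diameter, mm (>= 0).
#' @param config a [screen_config()] (or a threshold given via `threshold_mm`).
#' @param threshold_mm shortcut override of the threshold.
#' @return `"AAA"` or `"control"` (vectorized over `diameter_mm`).
#' @export
classify <- function(diameter_mm, config = screen_config(),
                     threshold_mm = config$threshold_mm) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm < 0))
    stop("diameter must be finite and >= 0")
  ifelse(diameter_mm > threshold_mm, "AAA", "control")
}

#' Confusion matrix and screening rates
#'
#' AAA is the positive class. Rates are returned both raw and rounded to
#' `rounding` decimal places (default integer percent). A zero denominator
#' yields NA (undefined), not 0.
#'
#' @param predicted,truth equal-length vectors of `"AAA"`/`"control"`.
#' @param rounding decimal places for the rounded percentages.
#' @return list with `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity` (rounded %), and `raw` (unrounded).
#' @export
cohort_metrics <- function(predicted, truth, rounding = 0) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  ok <- c("AAA", "control")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop('classes must be "AAA" or "control"')
  tp <- sum(predicted == "AAA" & truth == "AAA")
  fp <- sum(predicted == "AAA" & truth == "control")
  tn <- sum(predicted == "control" & truth == "control")
  fn <- sum(predicted == "control" & truth == "AAA")
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  raw <- list(accuracy = rate(tp + tn, tp + fp + tn + fn),
              sensitivity = rate(tp, tp + fn),
              specificity = rate(tn, tn + fp))
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = round(raw$accuracy, rounding),
       sensitivity = round(raw$sensitivity, rounding),
       specificity = round(raw$specificity, rounding),
       raw = raw)
}

#' Summary statistics of a measurement vector
#'
#' Mean, sample standard deviation (n - 1), median, IQR (p75 - p25), and the
#' 5th/95th percentiles, with percentiles by linear interpolation between
#' order statistics.
#'
#' @param values non-empty numeric vector (mm).
#' @return named list: `mean`, `sd`, `median`, `iqr`, `p5`, `p95`, `n`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values))) stop("values must be non-empty and finite")
  q <- quantile(values, c(0.05, 0.25, 0.75, 0.95), type = 7, names = FALSE)
  list(mean = mean(values), sd = if (length(values) > 1) sd(values) else 0,
       median = median(values), iqr = q[3] - q[2], p5 = q[1], p95 = q[4],
       n = length(values))
}

#' Absolute-error statistics of automatic vs manual diameters
#'
#' Per-case `|predicted - manual|` summarized overall and stratified by true
#' class when provided.
#'
#' @param predicted,manual paired diameter vectors (mm).
#' @param truth optional `"AAA"`/`"control"` vector for stratification.
#' @return list with `overall` and, when `truth` is given, `AAA` and
#'   `control` summaries (each as [summarize_values()]).
#' @export
error_stats <- function(predicted, manual, truth = NULL) {
  if (length(predicted) != length(manual)) stop("paired vectors must have equal length")
  err <- abs(predicted - manual)
  out <- list(overall = summarize_values(err))
  if (!is.null(truth)) {
    if (length(truth) != length(err)) stop("truth must match the pairs")
    if (any(truth == "AAA")) out$AAA <- summarize_values(err[truth == "AAA"])
    if (any(truth == "control")) out$control <- summarize_values(err[truth == "control"])
  }
  out
}

#' Screen a cohort manifest
#'
#' Measures and classifies every case in a manifest; cases that fail are
#' recorded with their stage-tagged error and excluded from metrics.
#'
#' @param manifest data.frame from [read_manifest()] (or a compatible one).
#' @param config a [screen_config()].
#' @param verbose print one line per case.
#' @return `cohort_report`: `cases` data.frame (case_id, predicted diameter,
#'   thrombus volume, classes, abs error), `metrics` (when manual diameters
#'   present), `diameter_stats`, `error_stats`, `failures`.
#' @export
screen_cohort <- function(manifest, config = screen_config(), verbose = FALSE) {
  rows <- list()
  failures <- list()
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    res <- tryCatch({
      masks <- load_case_masks(row)
      measure_case(masks$lumen, masks$thrombus, config, case_id = row$case_id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(case_id = row$case_id,
                                               error = conditionMessage(res))
      if (verbose) message(row$case_id, " FAILED: ", conditionMessage(res))
      next
    }
    manual <- if (!is.null(row$manual_diameter_mm)) row$manual_diameter_mm else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      case_id = row$case_id,
      predicted_diameter_mm = res$max_diameter_mm,
      manual_diameter_mm = manual,
      thrombus_volume_ml = res$thrombus_volume_ml,
      used_thrombus = res$used_thrombus,
      predicted_class = res$predicted_class,
      true_class = if (is.na(manual)) NA_character_
                   else classify(manual, config),
      abs_error_mm = if (is.na(manual)) NA_real_
                     else abs(res$max_diameter_mm - manual))
    if (verbose) message(sprintf("%s: %.1f mm -> %s", row$case_id,
                                 res$max_diameter_mm, res$predicted_class))
  }
  cases <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0))
  report <- list(cases = cases, failures = failures, config = config)
  if (nrow(cases) > 0 && any(!is.na(cases$true_class))) {
    ok <- !is.na(cases$true_class)
    report$metrics <- cohort_metrics(cases$predicted_class[ok],
                                     cases$true_class[ok], config$rounding)
    report$error_stats <- error_stats(cases$predicted_diameter_mm[ok],
                                      cases$manual_diameter_mm[ok],
                                      cases$true_class[ok])
    report$diameter_stats <- list(
      overall = summarize_values(cases$predicted_diameter_mm[ok]))
    for (cls in c("AAA", "control"))
      if (any(cases$true_class[ok] == cls))
        report$diameter_stats[[cls]] <-
          summarize_values(cases$predicted_diameter_mm[ok][cases$true_class[ok] == cls])
  }
  structure(report, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d case(s), %d failure(s)\n",
              nrow(x$cases), length(x$failures)))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  confusion: TP %d, FP %d, TN %d, FN %d\n", m$tp, m$fp, m$tn, m$fn))
    cat(sprintf("  accuracy %s%%, sensitivity %s%%, specificity %s%%\n",
                format(m$accuracy), format(m$sensitivity), format(m$specificity)))
  }
  invisible(x)
}

#' Bland-Altman data table (mean vs difference per case)
#'
#' @param report a [screen_cohort()] result with manual diameters.
#' @return data.frame with `case_id`, `mean_mm`, `diff_mm` (automatic - manual).
#' @export
bland_altman_table <- function(report) {
  cases <- report$cases
  ok <- !is.na(cases$manual_diameter_mm)
  data.frame(case_id = cases$case_id[ok],
             mean_mm = (cases$predicted_diameter_mm[ok] + cases$manual_diameter_mm[ok]) / 2,
             diff_mm = cases$predicted_diameter_mm[ok] - cases$manual_diameter_mm[ok])
}

#' Write cohort report files (CSV of cases + JSON of metrics)
#'
#' @param report a [screen_cohort()] result.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "cohort_cases.csv")
  jpath <- file.path(dir, "cohort_metrics.json")
  write.csv(report$cases, cpath, row.names = FALSE)
  payload <- list(n_cases = nrow(report$cases), n_failures = length(report$failures),
                  failures = report$failures)
  if (!is.null(report$metrics)) payload$metrics <- report$metrics
  if (!is.null(report$diameter_stats)) payload$diameter_stats <- report$diameter_stats
  if (!is.null(report$error_stats)) payload$error_stats <- report$error_stats
  jsonlite::write_json(payload, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(cpath, jpath))
}
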