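#' Mean red-minus-blue (R-B) value over a region of interest
#'
#' The per-pixel difference between the red and blue channels, averaged over
#' the ROI, is the 3CCD surrogate for tissue oxygenation: oxygenated and
#' deoxygenated hemoglobin absorb red and blue light differently, so the R-B
#' contrast falls as the limb desaturates. The subtraction is carried out in
#' a signed floating-point domain, so integer-typed input cannot wrap.
#'
#' @param frame A color (height x width x 3, R,G,B order) array.
#' @param roi An [roi()].
#' @return Scalar mean of (R - B) over the ROI.
#' @export
rb_value <- function(frame, roi) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L) {
    stop_limbperf("rb_value() needs a 3-channel color frame.", "limbperf_modality_error")
  }
  check_roi(roi, frame)
  patch <- roi_crop(frame, roi)
  mean(as.numeric(patch[, , 1]) - as.numeric(patch[, , 3]))
}

#' Mean infrared intensity over a region of interest
#'
#' @param frame A single-channel infrared matrix.
#' @param roi An [roi()].
#' @return Scalar mean ROI intensity.
#' @export
ir_mean <- function(frame, roi) {
  if (length(dim(frame)) == 3L && dim(frame)[3] > 1L) {
    stop_limbperf("ir_mean() needs a single-channel infrared frame.", "limbperf_modality_error")
  }
  if (length(dim(frame)) == 3L) frame <- frame[, , 1L]
  check_roi(roi, frame)
  mean(roi_crop(frame, roi))
}

#' Percent difference of a series from its baseline
#'
#' Each element is expressed as the signed percent change from the baseline
#' value: `100 * (v - v_base) / |v_base|`. Used to turn raw R-B series into
#' the canonical oxygenation profile.
#'
#' @param values Numeric series.
#' @param baseline_index Index of the baseline element, or `NULL` when
#'   `baseline` is supplied directly.
#' @param baseline Baseline value (e.g. the mean of all pre-occlusion
#'   samples); overrides `baseline_index`.
#' @return Numeric series of percent differences; the element at
#'   `baseline_index` is exactly 0.
#' @export
rb_percent_difference <- function(values, baseline_index = NULL, baseline = NULL) {
  if (is.null(baseline)) {
    if (is.null(baseline_index)) {
      stop_limbperf("Supply `baseline_index` or `baseline`.", "limbperf_validation_error")
    }
    baseline <- values[[baseline_index]]
  }
  if (!is_scalar_number(baseline) || baseline == 0) {
    stop_limbperf("Baseline R-B value must be a nonzero number.", "limbperf_baseline_error")
  }
  100 * (values - baseline) / abs(baseline)
}

#' Affine calibration from infrared intensity to temperature
#'
#' Fits `temperature = slope * intensity + intercept` from reference pairs:
#' an exact solve for two pairs, ordinary least squares for more. With two
#' pairs the calibration round-trips both reference points exactly.
#' Temperatures are degrees Fahrenheit throughout the package.
#'
#' @param intensity,temperature Numeric vectors of at least two reference
#'   pairs; intensities must not all be equal.
#' @return Object of class `temperature_calibration` with fields `slope`
#'   (degF per intensity unit, must be positive), `intercept` (degF), the
#'   reference pairs, and `unit = "F"`.
#' @export
temperature_calibration <- function(intensity, temperature) {
  if (length(intensity) < 2 || length(intensity) != length(temperature)) {
    stop_limbperf("Need at least two (intensity, temperature) reference pairs.",
                  "limbperf_calibration_error")
  }
  if (diff(range(intensity)) == 0) {
    stop_limbperf("Degenerate calibration: all reference intensities are equal.",
                  "limbperf_calibration_error")
  }
  if (length(intensity) == 2) {
    slope <- diff(temperature) / diff(intensity)
    intercept <- temperature[1] - slope * intensity[1]
  } else {
    fit <- lm(temperature ~ intensity)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
  }
  if (!is.finite(slope) || slope <= 0) {
    stop_limbperf("Calibration slope must be positive (warmer tissue is brighter).",
                  "limbperf_calibration_error")
  }
  structure(
    list(slope = slope, intercept = intercept,
         ref_intensity = as.numeric(intensity),
         ref_temperature = as.numeric(temperature), unit = "F"),
    class = "temperature_calibration"
  )
}

#' Convert infrared intensities to temperature
#'
#' @param intensities Numeric vector of mean ROI intensities.
#' @param cal A [temperature_calibration()].
#' @return Temperatures in degrees Fahrenheit.
#' @export
calibrate_temperature <- function(intensities, cal) {
  stopifnot(inherits(cal, "temperature_calibration"))
  cal$slope * intensities + cal$intercept
}

# inverse map, used for rendering synthetic infrared frames and round-trips
uncalibrate_temperature <- function(temperatures, cal) {
  (temperatures - cal$intercept) / cal$slope
}

#' Extract a per-timepoint perfusion profile from a tracked sequence
#'
#' Reduces every frame to its scalar ROI summary: mean R-B for color
#' sequences (reported both raw and as percent difference from baseline) or
#' mean infrared intensity (reported raw and, when a calibration is
#' available, as temperature in degF). The baseline is the mean over all
#' frames timestamped strictly before `occlusion_start` (more stable than a
#' single frame); set `baseline = "first_frame"` to use frame 1 alone.
#'
#' @param seq A [frame_sequence()].
#' @param track Optional `roi_track` from [track_roi()]; alternatively pass
#'   `roi` to use one fixed ROI for every frame.
#' @param roi Fixed [roi()] used when `track` is `NULL`.
#' @param calibration Optional [temperature_calibration()]; defaults to the
#'   one carried by the sequence.
#' @param baseline `"pre_occlusion"` (default) or `"first_frame"`.
#' @return A `perfusion_profile`: list with `modality`, `events`, `unit`,
#'   and `data`, a tibble with columns `time_min`, `raw_value`, `value`
#'   (percent difference or degF), `roi_row`, `roi_col`, `confidence`.
#' @export
extract_profile <- function(seq, track = NULL, roi = NULL, calibration = NULL,
                            baseline = c("pre_occlusion", "first_frame")) {
  stopifnot(inherits(seq, "frame_sequence"))
  baseline <- match.arg(baseline)
  if (is.null(track)) {
    if (is.null(roi)) stop_limbperf("Supply `track` or `roi`.", "limbperf_validation_error")
    check_roi(roi, seq$frames[[1]])
    track <- tibble(
      frame = seq_along(seq$frames), time_min = seq$times,
      row0 = roi$row0, col0 = roi$col0, height = roi$height, width = roi$width,
      confidence = 1
    )
  }
  if (nrow(track) != length(seq$frames)) {
    stop_limbperf("Track length must match the number of frames.", "limbperf_validation_error")
  }
  raw <- vapply(seq_len(nrow(track)), function(i) {
    r <- track_roi_at(track, i)
    if (seq$modality == "color3") rb_value(seq$frames[[i]], r) else ir_mean(seq$frames[[i]], r)
  }, numeric(1))

  if (seq$modality == "color3") {
    pre <- if (baseline == "pre_occlusion") {
      seq$times < seq$events[["occlusion_start"]]
    } else {
      seq_along(raw) == 1L
    }
    if (!any(pre)) {
      stop_limbperf("No pre-occlusion frames available for the baseline.",
                    "limbperf_baseline_error")
    }
    value <- rb_percent_difference(raw, baseline = mean(raw[pre]))
    unit <- "percent"
  } else {
    calibration <- calibration %||% seq$calibration
    if (is.null(calibration)) {
      value <- raw
      unit <- "intensity"
    } else {
      value <- calibrate_temperature(raw, calibration)
      unit <- "F"
    }
  }
  perfusion_profile(
    tibble(time_min = seq$times, raw_value = raw, value = value,
           roi_row = track$row0, roi_col = track$col0,
           confidence = track$confidence),
    modality = seq$modality, events = seq$events, unit = unit
  )
}
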