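#' Locate the landmark values of a perfusion profile
#'
#' Finds the points the slope features are built from: the baseline (mean of
#' pre-occlusion samples), the maximum-ischemia value (the windowed minimum
#' over the occlusion period, since both R-B and temperature fall during
#' ischemia), the maximum-reperfusion value (maximum within the first
#' `max_rpf_window` minutes after release, so the later post-reperfusion
#' slopes always measure the decay of the overshoot), and the
#' post-reperfusion readings nominally 5, 10 and 30 minutes after release
#' (taken at the nearest sampled timepoint within `post_tol` minutes, half
#' the nominal 5-minute sampling interval).
#'
#' Missing windows do not error: absent landmarks are returned as `NA` and
#' propagate into missing feature cells, which the classifier's
#' missing-data handling deals with downstream.
#'
#' @param profile A [perfusion_profile()].
#' @param max_rpf_window Search window (min after release) for the
#'   reperfusion maximum. Default 10.
#' @param post_offsets Nominal post-release offsets (min). Default 5, 10, 30.
#' @param post_tol Matching tolerance for post offsets (min). Default 2.5.
#' @param max_ischemia `"window_min"` (default) scans the whole occlusion
#'   window; `"last_pre_release"` uses the final sample at or before release.
#' @return A `landmark_set` list: `baseline`, `max_ischemia` (value, time),
#'   `max_reperfusion` (value, time), `post` (named vector `rpf5`, `rpf10`,
#'   `rpf30`), `release`, `modality`, `unit`.
#' @export
locate_landmarks <- function(profile, max_rpf_window = 10,
                             post_offsets = c(5, 10, 30), post_tol = 2.5,
                             max_ischemia = c("window_min", "last_pre_release")) {
  stopifnot(inherits(profile, "perfusion_profile"))
  max_ischemia <- match.arg(max_ischemia)
  t <- profile$data$time_min
  v <- profile$data$value
  occ <- profile$events[["occlusion_start"]]
  rel <- profile$events[["release"]]

  pre <- t < occ
  baseline <- if (any(pre)) mean(v[pre]) else NA_real_

  in_occ <- t >= occ & t <= rel
  if (max_ischemia == "last_pre_release") {
    idx <- which(t <= rel)
    i_mi <- if (length(idx)) max(idx) else integer(0)
  } else {
    i_mi <- which(in_occ)[which.min(v[in_occ])]
  }
  mi_val <- if (length(i_mi)) v[i_mi] else NA_real_
  mi_time <- if (length(i_mi)) t[i_mi] else NA_real_

  in_rpf <- t > rel & t <= rel + max_rpf_window
  i_mr <- which(in_rpf)[which.max(v[in_rpf])]
  mr_val <- if (length(i_mr)) v[i_mr] else NA_real_
  mr_time <- if (length(i_mr)) t[i_mr] else NA_real_

  post <- vapply(post_offsets, function(off) {
    d <- abs(t - (rel + off))
    i <- which.min(d)
    if (length(i) && d[i] <= post_tol) v[i] else NA_real_
  }, numeric(1))
  names(post) <- paste0("rpf", post_offsets)

  structure(
    list(baseline = baseline,
         max_ischemia = list(value = mi_val, time = mi_time),
         max_reperfusion = list(value = mr_val, time = mr_time),
         post = post, release = rel,
         modality = profile$modality, unit = profile$unit),
    class = "landmark_set"
  )
}

#' Slope of reperfusion
#'
#' Rise rate of the signal after release: the difference between the
#' maximum-reperfusion and maximum-ischemia values divided by the duration
#' of reperfusion, taken as release-to-time-of-reperfusion-maximum (the
#' definition under which a post-release overshoot yields a finite positive
#' slope). Set `duration = "fixed_10"` to divide by a fixed 10 minutes
#' instead.
#'
#' @param lm A `landmark_set` from [locate_landmarks()].
#' @param duration `"to_peak"` (default) or `"fixed_10"`.
#' @return Slope in profile units per minute (%/min or degF/min), or `NA`
#'   if either landmark is missing.
#' @export
slope_of_reperfusion <- function(lm, duration = c("to_peak", "fixed_10")) {
  stopifnot(inherits(lm, "landmark_set"))
  duration <- match.arg(duration)
  if (is.na(lm$max_ischemia$value) || is.na(lm$max_reperfusion$value)) return(NA_real_)
  dt <- if (duration == "fixed_10") 10 else lm$max_reperfusion$time - lm$release
  if (!is.finite(dt) || dt == 0) {
    stop_limbperf("Zero reperfusion duration.", "limbperf_validation_error")
  }
  (lm$max_reperfusion$value - lm$max_ischemia$value) / dt
}

#' Slope of post-occlusive reactive hyperemia (PORH)
#'
#' Rate of change from the reperfusion maximum to the reading at a nominal
#' post-release offset, divided by the elapsed time between them. Negative
#' when the hyperemic overshoot decays back toward baseline.
#'
#' @param lm A `landmark_set` from [locate_landmarks()].
#' @param offset Post-release offset in minutes: 5, 10, or 30.
#' @return Slope in profile units per minute, or `NA` if the post value is
#'   missing.
#' @export
slope_of_porh <- function(lm, offset = c(5, 10, 30)) {
  stopifnot(inherits(lm, "landmark_set"))
  offset <- match.arg(as.character(offset[1]), c("5", "10", "30"))
  offset <- as.numeric(offset)
  if (is.na(lm$max_reperfusion$value)) return(NA_real_)
  t_post <- lm$release + offset
  dt <- t_post - lm$max_reperfusion$time
  if (dt <= 0) {
    stop_limbperf(
      "PORH offset falls at or before the reperfusion maximum; period undefined.",
      "limbperf_validation_error"
    )
  }
  post <- lm$post[[paste0("rpf", offset)]]
  if (is.null(post) || is.na(post)) return(NA_real_)
  (post - lm$max_reperfusion$value) / dt
}

# canonical imaging feature names, in table order
imaging_feature_names <- function() {
  c("IR Slope Rpf",
    "IR Whole Leg Rpf5", "IR Whole Leg Rpf10", "IR Whole Leg Rpf30",
    "IR PORH Slope Rpf5", "IR PORH Slope Rpf10", "IR PORH Slope Rpf30",
    "3CCD Slope Rpf",
    "3CCD Whole Leg Rpf10", "3CCD Whole Leg Rpf30",
    "3CCD PORH Slope Rpf5", "3CCD PORH Slope Rpf10")
}

#' Build an animal's imaging feature record
#'
#' Reduces the two modality profiles to the 12 named imaging features used
#' by the outcome models: per modality, the slope of reperfusion, the raw
#' whole-leg values at the post-release offsets, and the PORH slopes.
#' Either modality may be absent (e.g. an equipment failure); its columns
#' become `NA` — missingness is data here, not an error.
#'
#' @param color Optional color-modality [perfusion_profile()].
#' @param infrared Optional infrared [perfusion_profile()].
#' @param ... Passed on to [locate_landmarks()].
#' @return One-row tibble with the 12 imaging feature columns.
#' @export
build_feature_vector <- function(color = NULL, infrared = NULL, ...) {
  if (is.null(color) && is.null(infrared)) {
    stop_limbperf("At least one modality profile is required.", "limbperf_validation_error")
  }
  feats <- setNames(rep(NA_real_, 12L), imaging_feature_names())
  if (!is.null(infrared)) {
    lm <- locate_landmarks(infrared, ...)
    feats[["IR Slope Rpf"]] <- safe_slope(slope_of_reperfusion, lm)
    feats[["IR Whole Leg Rpf5"]] <- lm$post[["rpf5"]]
    feats[["IR Whole Leg Rpf10"]] <- lm$post[["rpf10"]]
    feats[["IR Whole Leg Rpf30"]] <- lm$post[["rpf30"]]
    feats[["IR PORH Slope Rpf5"]] <- safe_slope(slope_of_porh, lm, 5)
    feats[["IR PORH Slope Rpf10"]] <- safe_slope(slope_of_porh, lm, 10)
    feats[["IR PORH Slope Rpf30"]] <- safe_slope(slope_of_porh, lm, 30)
  }
  if (!is.null(color)) {
    lm <- locate_landmarks(color, ...)
    feats[["3CCD Slope Rpf"]] <- safe_slope(slope_of_reperfusion, lm)
    feats[["3CCD Whole Leg Rpf10"]] <- lm$post[["rpf10"]]
    feats[["3CCD Whole Leg Rpf30"]] <- lm$post[["rpf30"]]
    feats[["3CCD PORH Slope Rpf5"]] <- safe_slope(slope_of_porh, lm, 5)
    feats[["3CCD PORH Slope Rpf10"]] <- safe_slope(slope_of_porh, lm, 10)
  }
  as_tibble(as.list(feats))
}

# landmark degeneracies become missing feature cells, not hard failures
safe_slope <- function(f, ...) {
  tryCatch(f(...), limbperf_error = function(e) NA_real_)
}
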