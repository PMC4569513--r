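#' Per-timepoint perfusion/oxygenation profile
#'
#' Container for one animal's time series from one modality: percent
#' difference of R-B from baseline for color (3CCD) data, temperature in
#' degF (or raw intensity) for infrared data, plus the procedure events
#' needed to window the series.
#'
#' @param data Tibble with at least `time_min` and `value`; optional
#'   `raw_value`, `roi_row`, `roi_col`, `confidence`.
#' @param modality `"color3"` or `"infrared"`.
#' @param events Named numeric vector with at least `occlusion_start` and
#'   `release` (minutes).
#' @param unit Value unit: `"percent"`, `"F"`, or `"intensity"`.
#' @return An object of class `perfusion_profile`.
#' @export
perfusion_profile <- function(data, modality = c("color3", "infrared"), events,
                              unit = NULL) {
  modality <- match.arg(modality)
  data <- as_tibble(data)
  if (!all(c("time_min", "value") %in% names(data))) {
    stop_limbperf("Profile data needs `time_min` and `value` columns.",
                  "limbperf_validation_error")
  }
  if (any(diff(data$time_min) <= 0)) {
    stop_limbperf("Profile times must be strictly increasing.", "limbperf_validation_error")
  }
  if (is.list(events)) events <- unlist(events)
  if (!all(c("occlusion_start", "release") %in% names(events))) {
    stop_limbperf("Profile events must name occlusion_start and release.",
                  "limbperf_validation_error")
  }
  unit <- unit %||% if (modality == "color3") "percent" else "F"
  structure(
    list(modality = modality, events = events[!is.na(events)], unit = unit,
         data = data),
    class = "perfusion_profile"
  )
}

#' @export
print.perfusion_profile <- function(x, ...) {
  cat(sprintf("<perfusion_profile> %s (%s), %d timepoints, t = %g..%g min\n",
              x$modality, x$unit, nrow(x$data),
              min(x$data$time_min), max(x$data$time_min)))
  print(utils::head(x$data, 4))
  invisible(x)
}

#' @export
as_tibble.perfusion_profile <- function(x, ...) x$data

#' Write / read a perfusion profile as CSV
#'
#' Plain CSV with the profile's samples (`time_min`, `raw_value`,
#' `percent_diff` or `temperature_F`, `roi_row`, `roi_col`, `confidence`);
#' the modality, unit and event times are kept in `#!`-prefixed header
#' comments so a profile round-trips through a single file.
#'
#' @param profile A [perfusion_profile()].
#' @param path CSV path.
#' @return `path` invisibly (write); a `perfusion_profile` (read).
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "perfusion_profile"))
  value_col <- profile_value_column(profile)
  d <- profile$data
  names(d)[names(d) == "value"] <- value_col
  hdr <- c(
    sprintf("#! modality: %s", profile$modality),
    sprintf("#! unit: %s", profile$unit),
    sprintf("#! event %s: %.10g", names(profile$events), profile$events)
  )
  body <- strsplit(readr::format_csv(d), "\n", fixed = TRUE)[[1]]
  writeLines(c(hdr, body), path)
  invisible(path)
}

profile_value_column <- function(profile) {
  switch(profile$unit,
    percent = "percent_diff",
    F = "temperature_F",
    "value"
  )
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#!", lines, value = TRUE)
  modality <- sub("^#! modality: ", "", grep("^#! modality:", hdr, value = TRUE))
  unit <- sub("^#! unit: ", "", grep("^#! unit:", hdr, value = TRUE))
  ev_lines <- grep("^#! event ", hdr, value = TRUE)
  events <- as.numeric(sub("^#! event [^:]+: ", "", ev_lines))
  names(events) <- sub("^#! event ([^:]+):.*$", "\\1", ev_lines)
  d <- readr::read_csv(I(lines[!grepl("^#!", lines)]), show_col_types = FALSE)
  vc <- intersect(c("percent_diff", "temperature_F", "value"), names(d))[1]
  names(d)[names(d) == vc] <- "value"
  perfusion_profile(d, modality = modality, events = events, unit = unit)
}
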