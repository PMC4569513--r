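#' Timestamped image stack for one imaging modality
#'
#' A `frame_sequence` bundles an ordered list of frames with their acquisition
#' times (minutes from procedure start) and the named procedure events needed
#' downstream (`occlusion_start`, `release`, and optionally `baseline`,
#' `end`). Color (3CCD) frames are height x width x 3 arrays in R,G,B order;
#' infrared frames are height x width matrices. Pixel intensities are stored
#' on a 0-255 scale as doubles.
#'
#' @param frames List of numeric arrays sharing dimensions.
#' @param times Numeric vector of acquisition times in minutes, strictly
#'   increasing, one per frame. Sampling is nominally every 5 minutes.
#' @param modality `"color3"` or `"infrared"`.
#' @param events Named numeric vector of event times (minutes). Must contain
#'   `occlusion_start` and `release` with
#'   `occlusion_start < release <= end`; `baseline` defaults to the first
#'   timestamp and `end` to the last. All events must fall inside the
#'   timestamp range.
#' @param calibration Optional [temperature_calibration()] carried alongside
#'   infrared sequences.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, times, modality = c("color3", "infrared"),
                           events, calibration = NULL) {
  modality <- match.arg(modality)
  if (!is.list(frames) || length(frames) == 0) {
    stop_limbperf("`frames` must be a non-empty list of arrays.", "limbperf_format_error")
  }
  frames <- lapply(frames, check_frame, modality = modality)
  dims <- vapply(frames, function(f) paste(dim2(f), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) {
    stop_limbperf("All frames must share the same dimensions.", "limbperf_format_error")
  }
  if (!is.numeric(times) || length(times) != length(frames)) {
    stop_limbperf("`times` must be numeric with one entry per frame.", "limbperf_validation_error")
  }
  if (any(diff(times) <= 0)) {
    stop_limbperf("`times` must be strictly increasing.", "limbperf_validation_error")
  }
  events <- as_event_times(events, times)
  structure(
    list(frames = frames, times = as.numeric(times), modality = modality,
         events = events, calibration = calibration),
    class = "frame_sequence"
  )
}

dim2 <- function(f) dim(f)[1:2]

check_frame <- function(f, modality) {
  if (!is.numeric(f)) {
    stop_limbperf("Frames must be numeric.", "limbperf_format_error")
  }
  storage.mode(f) <- "double"   # signed domain: R-B must never wrap around
  nd <- length(dim(f))
  if (modality == "color3") {
    if (nd != 3L || dim(f)[3] != 3L) {
      stop_limbperf(
        "color3 frames must carry exactly 3 channels (R,G,B).",
        "limbperf_modality_error"
      )
    }
  } else {
    if (nd == 3L && dim(f)[3] == 1L) f <- f[, , 1L]
    if (length(dim(f)) != 2L) {
      stop_limbperf(
        "infrared frames must be single-channel matrices.",
        "limbperf_modality_error"
      )
    }
  }
  f
}

as_event_times <- function(events, times) {
  if (is.list(events)) events <- unlist(events)
  if (is.null(names(events)) || !is.numeric(events)) {
    stop_limbperf("`events` must be a named numeric vector.", "limbperf_validation_error")
  }
  needed <- c("occlusion_start", "release")
  if (!all(needed %in% names(events))) {
    stop_limbperf("`events` must name occlusion_start and release.", "limbperf_validation_error")
  }
  if (!"baseline" %in% names(events)) events["baseline"] <- times[1]
  if (!"end" %in% names(events)) events["end"] <- times[length(times)]
  if (any(events < times[1] - 1e-9) || any(events > times[length(times)] + 1e-9)) {
    stop_limbperf("Event times fall outside the timestamp range.", "limbperf_validation_error")
  }
  if (!(events[["occlusion_start"]] < events[["release"]] &&
        events[["release"]] <= events[["end"]])) {
    stop_limbperf("Events must satisfy occlusion_start < release <= end.",
                  "limbperf_validation_error")
  }
  events[c("baseline", "occlusion_start", "release", "end")]
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim2(x$frames[[1]])
  cat(sprintf("<frame_sequence> %s, %d frames %dx%d, t = %g..%g min\n",
              x$modality, length(x$frames), d[1], d[2],
              x$times[1], x$times[length(x$times)]))
  cat("  events:", paste(sprintf("%s=%g", names(x$events), x$events), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Rectangular region of interest
#'
#' Pixel-coordinate rectangle, 0-based and half-open: rows
#' `row0 .. row0+height-1`, columns `col0 .. col0+width-1`.
#'
#' @param row0,col0 Top-left corner (0-based).
#' @param height,width Extent in pixels; the area must be at least 4 pixels.
#' @return An object of class `roi`.
#' @export
roi <- function(row0, col0, height, width) {
  vals <- c(row0 = row0, col0 = col0, height = height, width = width)
  if (any(vals != floor(vals)) || any(c(row0, col0) < 0) || height < 1 || width < 1) {
    stop_limbperf("ROI coordinates must be non-negative integers.", "limbperf_validation_error")
  }
  if (height * width < 4) {
    stop_limbperf("ROI area must be at least 4 pixels.", "limbperf_validation_error")
  }
  structure(as.list(vals), class = "roi")
}

roi_in_bounds <- function(r, frame) {
  d <- dim2(frame)
  r$row0 >= 0 && r$col0 >= 0 &&
    r$row0 + r$height <= d[1] && r$col0 + r$width <= d[2]
}

check_roi <- function(r, frame) {
  if (!inherits(r, "roi")) stop_limbperf("Expected an `roi` object.", "limbperf_validation_error")
  if (!roi_in_bounds(r, frame)) {
    stop_limbperf("ROI extends beyond the frame bounds.", "limbperf_validation_error")
  }
  invisible(r)
}

# crop a frame (2-D or 3-D) to an ROI; returns matrix or array
roi_crop <- function(frame, r) {
  rows <- (r$row0 + 1L):(r$row0 + r$height)
  cols <- (r$col0 + 1L):(r$col0 + r$width)
  if (length(dim(frame)) == 3L) frame[rows, cols, , drop = FALSE] else frame[rows, cols, drop = FALSE]
}

#' Read a frame sequence from disk
#'
#' Reads either a multi-frame TIFF (`<stem>.tif`/`.tiff`) or a directory of
#' zero-padded numbered PNG/TIFF frames, together with a YAML sidecar
#' (`<stem>.yaml`, or `metadata.yaml` inside the directory) that supplies the
#' timestamps, modality, event times and, for infrared data, optional
#' temperature-calibration reference pairs. TIFF samples are stored in
#' `[0, 1]` and rescaled to the package's 0-255 intensity convention.
#'
#' @param path Path to the TIFF stack or frame directory.
#' @param modality Expected modality; checked against both the sidecar and
#'   the channel count of the frames.
#' @param event_times Optional named numeric vector overriding the sidecar's
#'   events.
#' @return A [frame_sequence()].
#' @seealso [write_frame_sequence()]
#' @export
read_frame_sequence <- function(path, modality = NULL, event_times = NULL) {
  if (dir.exists(path)) {
    meta_path <- file.path(path, "metadata.yaml")
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$", full.names = TRUE))
    if (length(files) == 0) {
      stop_limbperf("No numbered PNG/TIFF frames found in directory.", "limbperf_format_error")
    }
    raw <- lapply(files, read_one_frame)
  } else {
    if (!file.exists(path)) stop_limbperf(paste0("No such file: ", path), "limbperf_format_error")
    meta_path <- paste0(sub("\\.tiff?$", "", path), ".yaml")
    raw <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(raw)) raw <- list(raw)
  }
  if (!file.exists(meta_path)) {
    stop_limbperf(paste0("Missing metadata sidecar: ", meta_path), "limbperf_format_error")
  }
  meta <- yaml::read_yaml(meta_path)
  modality <- modality %||% meta$modality
  if (!is.null(meta$modality) && !identical(modality, meta$modality)) {
    stop_limbperf("Requested modality disagrees with the sidecar metadata.",
                  "limbperf_modality_error")
  }
  events <- event_times %||% unlist(meta$events)
  cal <- NULL
  if (!is.null(meta$calibration)) {
    cal <- temperature_calibration(
      intensity = vapply(meta$calibration, function(p) p$intensity, numeric(1)),
      temperature = vapply(meta$calibration, function(p) p$temperature, numeric(1))
    )
  }
  frames <- lapply(raw, function(f) f * 255)
  frame_sequence(frames, times = unlist(meta$times), modality = modality,
                 events = events, calibration = cal)
}

read_one_frame <- function(f) {
  if (grepl("\\.png$", f)) png::readPNG(f) else tiff::readTIFF(f)
}

#' Write a frame sequence to disk
#'
#' Writes a 32-bit float multi-frame TIFF plus a YAML sidecar holding the
#' timestamps, modality, events and any temperature calibration, in the
#' layout [read_frame_sequence()] expects. Intensities are rescaled from the
#' in-memory 0-255 convention to TIFF's `[0, 1]`.
#'
#' @param seq A [frame_sequence()].
#' @param path Output TIFF path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_frame_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  frames01 <- lapply(seq$frames, function(f) pmin(pmax(f / 255, 0), 1))
  tiff::writeTIFF(frames01, path, bits.per.sample = 32L)
  meta <- list(
    modality = seq$modality,
    times = as.list(seq$times),
    events = as.list(seq$events)
  )
  if (!is.null(seq$calibration)) {
    cal <- seq$calibration
    meta$calibration <- lapply(seq_along(cal$ref_intensity), function(i) {
      list(intensity = cal$ref_intensity[i], temperature = cal$ref_temperature[i])
    })
  }
  yaml::write_yaml(meta, paste0(sub("\\.tiff?$", "", path), ".yaml"))
  invisible(path)
}
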