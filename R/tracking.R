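#' Track a region of interest through a frame sequence
#'
#' Template matching by normalized cross-correlation (NCC). The template is
#' the previous frame's ROI (re-anchored every frame, which tolerates slow
#' drift), and the match is searched over integer shifts within a window of
#' plus or minus a quarter of the ROI size around the previous position.
#' Color frames are collapsed to a luminance image (channel mean) before
#' matching. Per-frame confidence is the attained correlation, clamped to
#' `[0, 1]`.
#'
#' Ties between equally correlated shifts are broken toward the smallest
#' displacement, so a static sequence reproduces the initial ROI exactly. A
#' zero-variance template (e.g. a blank frame) cannot be matched; the track
#' then falls back to the previous ROI with confidence 0 and a warning.
#'
#' @param seq A [frame_sequence()].
#' @param initial [roi()] valid on the first frame.
#' @param search_frac Half-width of the search window as a fraction of the
#'   ROI height/width (default 1/4).
#' @return A tibble of class `roi_track` with one row per frame and columns
#'   `frame`, `time_min`, `row0`, `col0`, `height`, `width`, `confidence`.
#' @export
track_roi <- function(seq, initial, search_frac = 0.25) {
  stopifnot(inherits(seq, "frame_sequence"))
  check_roi(initial, seq$frames[[1]])
  n <- length(seq$frames)
  gray <- lapply(seq$frames, to_gray)
  sr <- max(1L, as.integer(round(initial$height * search_frac)))
  sc <- max(1L, as.integer(round(initial$width * search_frac)))
  # candidate shifts ordered by displacement so zero shift wins exact ties
  shifts <- expand.grid(dr = -sr:sr, dc = -sc:sc)
  shifts <- shifts[order(abs(shifts$dr) + abs(shifts$dc), abs(shifts$dr)), ]

  out <- matrix(NA_real_, nrow = n, ncol = 3,
                dimnames = list(NULL, c("row0", "col0", "confidence")))
  out[1, ] <- c(initial$row0, initial$col0, 1)
  cur <- initial
  warned <- FALSE
  for (i in seq_len(n)[-1]) {
    tmpl <- as.vector(roi_crop(gray[[i - 1]], cur))
    if (sd(tmpl) == 0) {
      if (!warned) {
        warn("Zero-variance tracking template; keeping previous ROI with confidence 0.")
        warned <- TRUE
      }
      out[i, ] <- c(cur$row0, cur$col0, 0)
      next
    }
    best <- -Inf
    best_r <- cur
    for (k in seq_len(nrow(shifts))) {
      cand <- cur
      cand$row0 <- cur$row0 + shifts$dr[k]
      cand$col0 <- cur$col0 + shifts$dc[k]
      if (!roi_in_bounds(cand, gray[[i]])) next
      patch <- as.vector(roi_crop(gray[[i]], cand))
      if (sd(patch) == 0) next
      r <- stats::cor(tmpl, patch)
      if (r > best + 1e-12) {
        best <- r
        best_r <- cand
      }
    }
    if (!is.finite(best)) {
      out[i, ] <- c(cur$row0, cur$col0, 0)
    } else {
      cur <- best_r
      out[i, ] <- c(cur$row0, cur$col0, max(0, min(1, best)))
    }
  }
  track <- tibble(
    frame = seq_len(n), time_min = seq$times,
    row0 = out[, "row0"], col0 = out[, "col0"],
    height = initial$height, width = initial$width,
    confidence = out[, "confidence"]
  )
  class(track) <- c("roi_track", class(track))
  track
}

to_gray <- function(frame) {
  if (length(dim(frame)) == 3L) (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3 else frame
}

track_roi_at <- function(track, i) {
  roi(track$row0[i], track$col0[i], track$height[i], track$width[i])
}
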