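# programmatic fixtures shared across the suite

# uniform color frame with optional per-channel matrices
color_frame <- function(h = 8, w = 8, R = 100, G = 100, B = 100) {
  expand <- function(x) if (is.matrix(x)) x else matrix(x, h, w)
  array(c(expand(R), expand(G), expand(B)), dim = c(h, w, 3))
}

ir_frame <- function(h = 8, w = 8, val = 100) {
  if (is.matrix(val)) val else matrix(val, h, w)
}

# minimal valid frame sequence: n frames at 5-min spacing
tiny_sequence <- function(frames, events = c(occlusion_start = 5, release = 10),
                          modality = "color3", times = NULL, ...) {
  times <- times %||% seq(0, by = 5, length.out = length(frames))
  frame_sequence(frames, times, modality, events, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# profile from explicit samples
make_profile <- function(times, values, occlusion_start, release,
                         modality = "color3", unit = NULL) {
  perfusion_profile(
    tibble::tibble(time_min = times, value = values),
    modality = modality,
    events = c(occlusion_start = occlusion_start, release = release),
    unit = unit
  )
}

# frames containing a translating Gaussian blob, for tracking tests
blob_frames <- function(n = 6, h = 30, w = 40, start = c(12, 10), step = c(0, 3),
                        sigma = 2.5, amplitude = 150, background = 20) {
  lapply(seq_len(n), function(k) {
    cy <- start[1] + step[1] * (k - 1)
    cx <- start[2] + step[2] * (k - 1)
    background + amplitude *
      outer(seq_len(h), seq_len(w),
            function(r, c) exp(-((r - cy)^2 + (c - cx)^2) / (2 * sigma^2)))
  })
}

# a small but class-balanced cohort config for fast tests
small_config <- function(...) {
  cohort_config(
    group_sizes = c(sham = 2, occlusion_3.5 = 4, tourniquet_3.5 = 4,
                    occlusion_4.7 = 4, tourniquet_4.7 = 4),
    simulate_exclusions = FALSE,
    ...
  )
}

# handmade landmark set for direct slope arithmetic
fake_landmarks <- function(baseline = 0, mi_val, mi_time, mr_val, mr_time,
                           post = c(rpf5 = NA, rpf10 = NA, rpf30 = NA),
                           release) {
  structure(
    list(baseline = baseline,
         max_ischemia = list(value = mi_val, time = mi_time),
         max_reperfusion = list(value = mr_val, time = mr_time),
         post = post, release = release, modality = "color3", unit = "percent"),
    class = "landmark_set"
  )
}
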