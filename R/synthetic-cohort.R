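#' Configuration for a synthetic hind-limb ischemia cohort
#'
#' Defines the study conditions the generator emulates: five experimental
#' arms (sham, 3.5 h occlusion, 3.5 h tourniquet, 4.7 h occlusion, 4.7 h
#' tourniquet; sizes 5/5/5/6/5 = 26 animals), imaging at nominal 5-minute
#' intervals with 30 minutes of post-release follow-up, ischemia durations
#' of 210 and 282 minutes, group recovery rates of 75% (3.5 h arms) and
#' 25% (4.7 h arms), and simulated attrition (2 expired animals, 2 imaging
#' equipment failures) leaving 22 usable animals.
#'
#' Severity is a per-arm scalar that scales the ischemic signal drop, the
#' hyperemic overshoot, and the chemistry amplitudes; tourniquet arms are
#' more severe than occlusion arms of the same duration, and 4.7 h arms
#' more severe than 3.5 h arms. The recovery outcome is drawn from a
#' logistic link on two standardized imaging ground-truth features (the
#' infrared whole-leg value 5 min post-release and the 3CCD PORH decay
#' slope) with effect size `beta`; the per-group intercept is calibrated
#' numerically so the marginal recovery rate matches the configured group
#' rate at any `beta`.
#'
#' @param group_sizes Named integer vector of arm sizes.
#' @param sampling_interval Minutes between frames (default 5).
#' @param baseline_lead Nominal minutes of pre-occlusion baseline imaging
#'   (default 15; the actual occlusion start is shifted so that release
#'   falls on the sampling grid).
#' @param durations_min Ischemia durations in minutes for the 3.5 h and
#'   4.7 h arms.
#' @param follow_up Minutes of post-release imaging (default 30).
#' @param severity Named per-arm severity scalars (sham 0).
#' @param recovery_prob Named recovery probabilities for `sham`, `3.5`,
#'   `4.7`.
#' @param beta Outcome effect size linking imaging features to recovery.
#' @param image_dim Frame size (rows, cols) for rendered frames.
#' @param pixel_noise Per-pixel Gaussian noise sd (0-255 intensity units).
#' @param profile_noise Named sd of profile-level noise: `color` (raw R-B
#'   units) and `infrared` (degF).
#' @param lab_noise Log-normal sdlog of chemistry draws.
#' @param roi_drift Per-frame drift of the limb (rows, cols, pixels) to
#'   exercise ROI tracking; default none.
#' @param peak_offsets Candidate times (min after release) of the 3CCD
#'   hyperemic peak; sub-interval values emulate the extra video frame
#'   grabbed as the overshoot crests.
#' @param simulate_exclusions Simulate the 2 expired animals (post-op data
#'   dropped) and 2 equipment failures (color sequence truncated at
#'   release).
#' @param ir_calibration Infrared [temperature_calibration()] used to
#'   render and read back IR frames.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    group_sizes = c(sham = 5, occlusion_3.5 = 5, tourniquet_3.5 = 5,
                    occlusion_4.7 = 6, tourniquet_4.7 = 5),
    sampling_interval = 5,
    baseline_lead = 15,
    durations_min = c("3.5" = 210, "4.7" = 282),
    follow_up = 30,
    severity = c(sham = 0, occlusion_3.5 = 1, tourniquet_3.5 = 1.4,
                 occlusion_4.7 = 1.7, tourniquet_4.7 = 2.1),
    recovery_prob = c(sham = 0.99, "3.5" = 0.75, "4.7" = 0.25),
    beta = 2,
    image_dim = c(48, 64),
    pixel_noise = 1,
    profile_noise = c(color = 0.25, infrared = 0.3),
    lab_noise = 0.15,
    roi_drift = c(0, 0),
    peak_offsets = c(1.5, 2.5, 3.5),
    simulate_exclusions = TRUE,
    ir_calibration = temperature_calibration(c(100, 200), c(70, 120))) {
  if (any(group_sizes < 0) || sum(group_sizes) == 0) {
    stop_limbperf("Group sizes must be non-negative and sum to > 0.",
                  "limbperf_validation_error")
  }
  stopifnot(all(durations_min > 0), all(recovery_prob >= 0 & recovery_prob <= 1))
  structure(
    list(group_sizes = group_sizes, sampling_interval = sampling_interval,
         baseline_lead = baseline_lead, durations_min = durations_min,
         follow_up = follow_up, severity = severity,
         recovery_prob = recovery_prob, beta = beta, image_dim = image_dim,
         pixel_noise = pixel_noise, profile_noise = profile_noise,
         lab_noise = lab_noise, roi_drift = roi_drift,
         peak_offsets = peak_offsets,
         simulate_exclusions = simulate_exclusions,
         ir_calibration = ir_calibration),
    class = "cohort_config"
  )
}

group_duration_label <- function(group) {
  ifelse(grepl("4\\.7", group), "4.7", ifelse(grepl("3\\.5", group), "3.5", "sham"))
}

# release is snapped to the sampling grid; occlusion start shifts to keep
# the configured ischemia duration exact
group_timeline <- function(group, config) {
  lab <- group_duration_label(group)
  dur <- if (lab == "sham") config$durations_min[["3.5"]] else config$durations_min[[lab]]
  dt <- config$sampling_interval
  release <- dt * round((config$baseline_lead + dur) / dt)
  occ <- release - dur
  list(occlusion_start = occ, release = release, end = release + config$follow_up,
       times = seq(0, release + config$follow_up, by = dt))
}

# piecewise oxygenation curve in percent-from-baseline units:
# flat baseline, fast exponential drop + slow linear decline during
# occlusion, linear rise to the hyperemic peak shortly after release, then
# exponential decay (tau ~ 6 min) back toward an almost-baseline residual
color_curve_pct <- function(t, par, tl, decay_tau = 6) {
  occ <- tl$occlusion_start; rel <- tl$release
  peak_t <- rel + par$t_peak
  pct_occl <- function(tt) {
    -(par$drop_pct * (1 - exp(-(tt - occ) / 15)) + par$slow_pct * (tt - occ))
  }
  rise_from <- pct_occl(rel)
  vapply(t, function(tt) {
    if (tt < occ) 0
    else if (tt <= rel) pct_occl(tt)
    else if (tt <= peak_t) rise_from + (par$overshoot_pct - rise_from) * (tt - rel) / par$t_peak
    else par$resid_pct + (par$overshoot_pct - par$resid_pct) *
        exp(-(tt - peak_t) / decay_tau)
  }, numeric(1))
}

# infrared temperature curve (degF): linear decline during occlusion,
# monotone saturating recovery after release, no overshoot; 4.7 h arms
# recover only a fraction of the drop within the follow-up window
ir_curve_F <- function(t, par, tl) {
  occ <- tl$occlusion_start; rel <- tl$release
  dur <- rel - occ
  t_rel_val <- par$temp_baseline_F - par$ir_drop_F
  k <- 0.08
  span <- (par$temp_baseline_F - t_rel_val) * par$recov_frac
  denom <- 1 - exp(-k * tl$end + k * rel)
  vapply(t, function(tt) {
    if (tt < occ) par$temp_baseline_F
    else if (tt <= rel) par$temp_baseline_F - par$ir_drop_F * (tt - occ) / dur
    else t_rel_val + span * (1 - exp(-k * (tt - rel))) / denom
  }, numeric(1))
}

# analytic imaging features of the noise-free curves at the sampled times
true_imaging_features <- function(par, tl) {
  ct <- sort(unique(c(tl$times, tl$release + par$t_peak)))
  rel <- tl$release
  col_pct <- color_curve_pct(ct, par, tl)
  irF <- ir_curve_F(tl$times, par, tl)
  at <- function(tt, times, vals) vals[which.min(abs(times - tt))]

  col_mi <- min(col_pct[ct >= tl$occlusion_start & ct <= rel])
  col_peak <- par$overshoot_pct
  ir_mi <- min(irF[tl$times >= tl$occlusion_start & tl$times <= rel])
  ir_rpf <- function(off) at(rel + off, tl$times, irF)
  ir_peak_t <- 10  # monotone recovery: window max sits at the window edge
  ir_peak <- ir_rpf(10)
  col_rpf <- function(off) at(rel + off, ct, col_pct)
  porh_slope <- function(off) (col_rpf(off) - par$overshoot_pct) / (off - par$t_peak)

  tibble(
    "IR Slope Rpf" = (ir_peak - ir_mi) / ir_peak_t,
    "IR Whole Leg Rpf5" = ir_rpf(5),
    "IR Whole Leg Rpf10" = ir_rpf(10),
    "IR Whole Leg Rpf30" = ir_rpf(30),
    "IR PORH Slope Rpf5" = NA_real_,   # undefined: IR maximum sits at +10
    "IR PORH Slope Rpf10" = NA_real_,
    "IR PORH Slope Rpf30" = (ir_rpf(30) - ir_peak) / 20,
    "3CCD Slope Rpf" = (col_peak - col_mi) / par$t_peak,
    "3CCD Whole Leg Rpf10" = col_rpf(10),
    "3CCD Whole Leg Rpf30" = col_rpf(30),
    "3CCD PORH Slope Rpf5" = porh_slope(5),
    "3CCD PORH Slope Rpf10" = porh_slope(10)
  )
}

# E_{Z~N(0,1)}[plogis(c + beta Z)] = p, solved for the intercept c
calibrate_recovery_intercept <- function(p, beta) {
  if (p <= 1e-12) return(-40)
  if (p >= 1 - 1e-12) return(40)
  if (abs(beta) < 1e-12) return(stats::qlogis(p))
  marg <- function(c) {
    stats::integrate(function(z) stats::plogis(c + beta * z) * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value - p
  }
  uniroot(marg, c(-40, 40), tol = 1e-9)$root
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-animal profile parameters, recovery outcomes, functional and
#' pathology scores, and chemistry amplitudes for the configured arms, and
#' records the full ground truth (including analytic imaging features of
#' the noise-free curves) alongside. With the default configuration 26
#' animals are generated and 4 are marked excluded (2 expired, 2 equipment
#' failures), leaving 22 usable. Fully deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `synthetic_cohort` list: `animals` (tibble with group,
#'   outcome, scores, exclusion flags), `ground_truth` (per-animal curve
#'   and lab parameters plus child seeds), `true_features` (analytic
#'   imaging features), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    n <- length(groups)
    sev_g <- config$severity[groups]
    animals <- tibble(
      animal_id = sprintf("A%02d", seq_len(n)),
      group = groups,
      duration_label = group_duration_label(groups),
      severity = unname(sev_g)
    )

    gt <- purrr::pmap_dfr(animals, function(animal_id, group, duration_label, severity) {
      is_sham <- severity == 0
      tibble(
        animal_id = animal_id,
        rb_baseline_raw = rnorm(1, 40, 3),
        drop_pct = if (is_sham) abs(rnorm(1, 0.5, 0.2)) else 10 + 5 * severity + rnorm(1, 0, 1.5),
        slow_pct = if (is_sham) 0 else 0.01 + 0.005 * severity,
        overshoot_pct = if (is_sham) abs(rnorm(1, 0.5, 0.2)) else
          pmax(1, 5 + 2.5 * severity + rnorm(1, 0, 1)),
        t_peak = sample(config$peak_offsets, 1),
        resid_frac = runif(1, 0.05, 0.25),
        temp_baseline_F = rnorm(1, 101.5, 0.7),
        ir_drop_F = if (is_sham) abs(rnorm(1, 0.3, 0.1)) else
          pmax(0.5, 1.5 + 2 * severity + rnorm(1, 0, 0.3)),
        recov_frac = if (duration_label == "4.7") runif(1, 0.55, 0.75) else runif(1, 0.95, 1),
        lab_amp = exp(rnorm(1, 0, 0.2)),
        profile_seed = sample.int(2^30, 1),
        frame_seed = sample.int(2^30, 1),
        lab_seed = sample.int(2^30, 1)
      )
    })
    gt$resid_pct <- gt$resid_frac * gt$overshoot_pct

    tf <- purrr::map_dfr(seq_len(n), function(i) {
      tl <- group_timeline(animals$group[i], config)
      dplyr::bind_cols(tibble(animal_id = animals$animal_id[i]),
                       true_imaging_features(as.list(gt[i, ]), tl))
    })

    out <- generate_outcomes(tf, animals, config)
    animals <- dplyr::left_join(animals, out, by = "animal_id")

    # attrition: expired animals lose post-operative data; equipment
    # failures lose the post-release color sequence
    animals$excluded <- FALSE
    animals$exclusion_reason <- NA_character_
    gt$color_truncate_at <- NA_real_
    if (isTRUE(config$simulate_exclusions) && n >= 8) {
      sham_idx <- which(animals$group == "sham")
      occ47_idx <- which(animals$group == "occlusion_4.7")
      expired <- c(sham_idx[1], occ47_idx[1])
      expired <- expired[!is.na(expired)]
      pool <- setdiff(seq_len(n), expired)
      equip <- sample(pool, min(2, length(pool)))
      animals$excluded[c(expired, equip)] <- TRUE
      animals$exclusion_reason[expired] <- "expired"
      animals$exclusion_reason[equip] <- "equipment_malfunction"
      for (j in expired) {
        animals[j, c("tarlov_d1", "tarlov_d2", "tarlov_d3", "tarlov_d7",
                     "drop_foot", "pathology_muscle")] <- NA
        animals$recovered[j] <- NA
      }
      for (j in equip) {
        tl <- group_timeline(animals$group[j], config)
        gt$color_truncate_at[j] <- tl$release + 1
      }
    }
    animals$outcome <- ifelse(is.na(animals$recovered), NA_character_,
                              ifelse(animals$recovered, "recovered", "not_recovered"))
    animals$usable <- !animals$excluded

    structure(
      list(animals = animals, ground_truth = gt, true_features = tf,
           config = config, seed = seed),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d animals (%d usable), seed %s\n",
              nrow(x$animals), sum(x$animals$usable), format(x$seed)))
  print(dplyr::count(x$animals, .data$group, .data$outcome))
  invisible(x)
}

#' Draw recovery outcomes and functional scores from imaging ground truth
#'
#' The probability of full recovery is a logistic function of the two
#' discriminative imaging features (infrared whole-leg value 5 min
#' post-release, and the 3CCD PORH decay slope), standardized within arm,
#' with slope `beta`; the per-arm intercept is calibrated so the marginal
#' recovery rate equals the configured arm rate. Tarlov trajectories are
#' consistent with the outcome (recovered animals reach 5 by day 7,
#' non-recovered stay at 4 or below), drop-foot scores run higher in the
#' 4.7 h arms, and muscle pathology subscores scale with severity.
#'
#' @param true_features Tibble of analytic imaging features (from
#'   [generate_cohort()]'s ground truth).
#' @param animals Tibble with `animal_id`, `group`, `severity`.
#' @param config A [cohort_config()].
#' @return Tibble with `animal_id`, `p_recover`, `recovered`, Tarlov
#'   scores, `drop_foot`, pathology subscores and `pathology_muscle`.
#' @export
generate_outcomes <- function(true_features, animals, config) {
  z_within <- function(x, g) {
    stats::ave(x, g, FUN = function(v) {
      s <- sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
  }
  u <- z_within(true_features[["IR Whole Leg Rpf5"]], animals$group) +
    z_within(true_features[["3CCD PORH Slope Rpf5"]], animals$group)
  u <- z_within(u, animals$group)

  dur <- group_duration_label(animals$group)
  p_group <- config$recovery_prob[dur]
  cpt <- vapply(unique(dur), function(dl) {
    calibrate_recovery_intercept(config$recovery_prob[[dl]], config$beta)
  }, numeric(1))
  eta <- cpt[dur] + config$beta * u
  p <- stats::plogis(eta)
  rec <- runif(length(p)) < p

  sev <- animals$severity
  n <- length(rec)
  tarlov_d7 <- ifelse(rec, 5L, pmax(2L, 4L - rbinom(n, 1, pmin(0.9, sev / 3))))
  tarlov_d1 <- pmax(0L, tarlov_d7 - 1L - rbinom(n, 2, pmin(0.9, sev / 3)))
  tarlov_d2 <- pmin(tarlov_d7, tarlov_d1 + rbinom(n, 1, 0.7))
  tarlov_d3 <- pmin(tarlov_d7, tarlov_d2 + rbinom(n, 1, 0.7))
  drop_foot <- ifelse(dur == "4.7",
                      pmin(3L, 1L + rbinom(n, 2, 0.5) - as.integer(rec)),
                      rbinom(n, 1, ifelse(rec, 0.05, 0.3)))
  drop_foot <- pmax(0L, drop_foot)

  subs <- vapply(c("edema", "inflammation", "degeneration", "necrosis", "regeneration"),
                 function(s) rbinom(n, 5, pmin(0.85, sev / 4)), integer(n))
  path <- pathology_total(subs[, 1], subs[, 2], subs[, 3], subs[, 4], subs[, 5])

  tibble(
    animal_id = true_features$animal_id,
    p_recover = p, recovered = rec,
    tarlov_d1 = tarlov_d1, tarlov_d2 = tarlov_d2, tarlov_d3 = tarlov_d3,
    tarlov_d7 = tarlov_d7, drop_foot = as.integer(drop_foot),
    edema = subs[, 1], inflammation = subs[, 2], degeneration = subs[, 3],
    necrosis = subs[, 4], regeneration = subs[, 5],
    pathology_muscle = path
  )
}

cohort_row <- function(cohort, animal_id) {
  i <- match(animal_id, cohort$animals$animal_id)
  if (is.na(i)) stop_limbperf("Unknown animal id.", "limbperf_validation_error")
  i
}

#' Generate an animal's noise-added perfusion profiles
#'
#' Samples the animal's ground-truth curves at the acquisition times (the
#' 3CCD series carries one extra sample at the hyperemic peak, emulating
#' the frame grabbed from continuous video as the overshoot crests), adds
#' Gaussian profile noise, and returns ready-made [perfusion_profile()]s —
#' the fast path that bypasses frame rendering. Equipment-failure animals
#' get a color series truncated at release.
#'
#' @param cohort A [generate_cohort()] result.
#' @param animal_id Animal id string.
#' @param noise Multiplier on the configured profile noise (0 = noise-free).
#' @return List with `color` and `infrared` [perfusion_profile()]s.
#' @export
generate_profiles <- function(cohort, animal_id, noise = 1) {
  i <- cohort_row(cohort, animal_id)
  config <- cohort$config
  par <- as.list(cohort$ground_truth[i, ])
  tl <- group_timeline(cohort$animals$group[i], config)
  with_seed(par$profile_seed, {
    ct <- sort(unique(c(tl$times, tl$release + par$t_peak)))
    if (!is.na(par$color_truncate_at)) ct <- ct[ct <= par$color_truncate_at]
    raw_rb <- par$rb_baseline_raw * (1 + color_curve_pct(ct, par, tl) / 100) +
      rnorm(length(ct), 0, noise * config$profile_noise[["color"]])
    col_events <- c(occlusion_start = tl$occlusion_start, release = tl$release,
                    end = max(ct))
    color <- perfusion_profile(
      tibble(time_min = ct, raw_value = raw_rb,
             value = rb_percent_difference(raw_rb, baseline = mean(raw_rb[ct < tl$occlusion_start]))),
      modality = "color3", events = col_events, unit = "percent"
    )
    tempF <- ir_curve_F(tl$times, par, tl) +
      rnorm(length(tl$times), 0, noise * config$profile_noise[["infrared"]])
    infrared <- perfusion_profile(
      tibble(time_min = tl$times,
             raw_value = uncalibrate_temperature(tempF, config$ir_calibration),
             value = tempF),
      modality = "infrared",
      events = c(occlusion_start = tl$occlusion_start, release = tl$release,
                 end = tl$end),
      unit = "F"
    )
    list(color = color, infrared = infrared)
  })
}

#' Render an animal's frame sequences
#'
#' Renders the ground-truth curves into image stacks: the limb is a simple
#' elliptical region (high R-B contrast / warm) on a neutral background —
#' enough structure to exercise ROI tracking and the channel arithmetic,
#' with no anatomical realism. Optional per-frame drift translates the limb
#' to exercise the tracker; per-pixel Gaussian noise is added on top.
#'
#' @inheritParams generate_profiles
#' @param noise Multiplier on the configured pixel noise.
#' @param drift Per-frame (rows, cols) drift in pixels; defaults to the
#'   configured `roi_drift`.
#' @return List with `color` and `infrared` [frame_sequence()]s, plus
#'   `limb_centers`, the ground-truth ellipse centers per frame (rows =
#'   frames; color sequence indexing).
#' @export
generate_imaging_series <- function(cohort, animal_id, noise = 1, drift = NULL) {
  i <- cohort_row(cohort, animal_id)
  config <- cohort$config
  par <- as.list(cohort$ground_truth[i, ])
  tl <- group_timeline(cohort$animals$group[i], config)
  drift <- drift %||% config$roi_drift
  h <- config$image_dim[1]; w <- config$image_dim[2]
  cy0 <- h / 2; cx0 <- w / 2
  ry <- 0.30 * h; rx <- 0.38 * w

  with_seed(par$frame_seed, {
    ct <- sort(unique(c(tl$times, tl$release + par$t_peak)))
    if (!is.na(par$color_truncate_at)) ct <- ct[ct <= par$color_truncate_at]
    rb_t <- par$rb_baseline_raw * (1 + color_curve_pct(ct, par, tl) / 100)
    temp_t <- ir_curve_F(tl$times, par, tl)
    int_t <- uncalibrate_temperature(temp_t, config$ir_calibration)

    limb_mask <- function(k) {
      cy <- cy0 + drift[1] * (k - 1)
      cx <- cx0 + drift[2] * (k - 1)
      outer(seq_len(h), seq_len(w),
            function(r, c) ((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1)
    }
    sdpx <- noise * config$pixel_noise
    color_frames <- lapply(seq_along(ct), function(k) {
      m <- limb_mask(k)
      R <- matrix(40, h, w); B <- matrix(40, h, w); G <- matrix(40, h, w)
      R[m] <- 60 + rb_t[k]; B[m] <- 60; G[m] <- 90
      fr <- array(c(R, G, B), dim = c(h, w, 3))
      if (sdpx > 0) fr <- fr + array(rnorm(length(fr), 0, sdpx), dim = dim(fr))
      fr
    })
    ir_frames <- lapply(seq_along(tl$times), function(k) {
      m <- limb_mask(k)
      f <- matrix(60, h, w)
      f[m] <- int_t[k]
      if (sdpx > 0) f <- f + matrix(rnorm(length(f), 0, sdpx), h, w)
      f
    })
    centers <- tibble(
      frame = seq_along(ct),
      row = cy0 + drift[1] * (seq_along(ct) - 1),
      col = cx0 + drift[2] * (seq_along(ct) - 1)
    )
    list(
      color = frame_sequence(color_frames, ct, "color3",
                             c(occlusion_start = tl$occlusion_start,
                               release = tl$release, end = max(ct))),
      infrared = frame_sequence(ir_frames, tl$times, "infrared",
                                c(occlusion_start = tl$occlusion_start,
                                  release = tl$release, end = tl$end),
                                calibration = config$ir_calibration),
      limb_centers = centers
    )
  })
}

# chemistry trajectory shapes: log-time triangle bump peaking at tp
lab_kernel <- function(t, tp, width = 1.2) {
  pmax(0, 1 - abs(log1p(t) - log1p(tp)) / width)
}

lab_panel <- function(release) {
  tibble(
    analyte = c("BUN", "ALT", "AST", "LDH", "CK", "Creatinine", "K+", "CO2", "BE"),
    baseline = c(9, 65, 36, 1000, 800, 1.1, 5.3, 28, 3),
    peak_time = c(release + 180, 4320, 1440, 1440, 1440, 1440, 10080, release + 180, release + 180),
    amp = c(0.5, 0.4, 1.5, 1.2, 6, 0.15, 0.2, -0.2, -0.5)
  )
}

#' Generate an animal's blood chemistry draws
#'
#' Long-format chemistry trajectories on the draw schedule (baseline,
#' maximum ischemia, 30 min and 3 h post-reperfusion, and days 1, 3, 7 at
#' 1440/4320/10080 min): each analyte follows a log-time bump whose
#' amplitude scales with ischemia severity, peaking at the characteristic
#' times (CK/AST/LDH at day 1, ALT at day 3, BUN 3 h post-reperfusion,
#' bicarbonate nadir before 24 h, potassium still climbing at day 7), with
#' multiplicative log-normal noise. Two cytokine columns (IL-6, TNF-a) are
#' generated as pure noise — deliberately uninformative. Sham amplitudes
#' stay in the baseline band.
#'
#' @inheritParams generate_profiles
#' @param noise Multiplier on the configured log-normal noise.
#' @return Long tibble: `animal_id`, `timepoint_min`, `analyte`, `value`.
#' @export
generate_labs <- function(cohort, animal_id, noise = 1) {
  i <- cohort_row(cohort, animal_id)
  config <- cohort$config
  par <- as.list(cohort$ground_truth[i, ])
  sev <- cohort$animals$severity[i]
  tl <- group_timeline(cohort$animals$group[i], config)
  sched <- c(0, tl$release, tl$release + 30, tl$release + 180, 1440, 4320, 10080)
  panel <- lab_panel(tl$release)
  with_seed(par$lab_seed, {
    out <- purrr::pmap_dfr(panel, function(analyte, baseline, peak_time, amp) {
      shape <- lab_kernel(sched, peak_time)
      val <- baseline * (1 + amp * (sev / 2) * par$lab_amp * shape)
      val <- val * exp(rnorm(length(sched), 0, noise * config$lab_noise))
      tibble(animal_id = cohort$animals$animal_id[i], timepoint_min = sched,
             analyte = analyte, value = pmax(val, 0))
    })
    cyto <- purrr::map_dfr(c("IL-6", "TNF-a"), function(cy) {
      tibble(animal_id = cohort$animals$animal_id[i], timepoint_min = sched,
             analyte = cy,
             value = 30 * exp(rnorm(length(sched), 0, 0.8)))
    })
    dplyr::bind_rows(out, cyto)
  })
}
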