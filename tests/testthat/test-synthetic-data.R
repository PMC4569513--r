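test_that("default cohort reproduces the experimental design counts", {
  co <- generate_cohort(cohort_config(), seed = 1)
  expect_equal(nrow(co$animals), 26)
  expect_equal(sum(co$animals$usable), 22)
  expect_equal(sum(co$animals$excluded), 4)
  counts <- table(co$animals$group)
  expect_equal(as.integer(counts[c("sham", "occlusion_3.5", "tourniquet_3.5",
                                   "occlusion_4.7", "tourniquet_4.7")]),
               c(5L, 5L, 5L, 6L, 5L))
  reasons <- co$animals$exclusion_reason[co$animals$excluded]
  expect_equal(sum(reasons == "expired"), 2)
  expect_equal(sum(reasons == "equipment_malfunction"), 2)
  # expired animals lose their post-operative outcome
  expired <- co$animals[which(co$animals$exclusion_reason == "expired"), ]
  expect_true(all(is.na(expired$outcome)))
  expect_true(all(is.na(expired$tarlov_d7)))
})

test_that("cohort generation is fully deterministic under a fixed seed", {
  c1 <- generate_cohort(cohort_config(), seed = 99)
  c2 <- generate_cohort(cohort_config(), seed = 99)
  expect_identical(c1$animals, c2$animals)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(c1$true_features, c2$true_features)
  p1 <- generate_profiles(c1, "A05")
  p2 <- generate_profiles(c2, "A05")
  expect_identical(p1$color$data, p2$color$data)
  l1 <- generate_labs(c1, "A09")
  l2 <- generate_labs(c2, "A09")
  expect_identical(l1, l2)
  s1 <- generate_imaging_series(c1, "A02")
  s2 <- generate_imaging_series(c2, "A02")
  expect_identical(s1$color$frames[[3]], s2$color$frames[[3]])

  expect_error(generate_cohort(cohort_config(group_sizes = c(sham = 0))),
               class = "limbperf_validation_error")
})

test_that("noise-free profiles equal the ground-truth curves at sample times", {
  co <- generate_cohort(small_config(), seed = 4)
  for (aid in c("A03", "A07", "A13")) {
    i <- match(aid, co$animals$animal_id)
    par <- as.list(co$ground_truth[i, ])
    tl <- limbperf:::group_timeline(co$animals$group[i], co$config)
    prof <- generate_profiles(co, aid, noise = 0)
    expect_equal(prof$color$data$value,
                 limbperf:::color_curve_pct(prof$color$data$time_min, par, tl),
                 tolerance = 1e-9)
    expect_equal(prof$infrared$data$value,
                 limbperf:::ir_curve_F(prof$infrared$data$time_min, par, tl),
                 tolerance = 1e-9)
  }
})

test_that("noise-free dynamics show the expected ischemia/reperfusion shape", {
  co <- generate_cohort(small_config(), seed = 12)
  nonsham <- co$animals$animal_id[co$animals$group != "sham"]
  for (aid in nonsham[seq(1, length(nonsham), by = 3)]) {
    prof <- generate_profiles(co, aid, noise = 0)
    cd <- prof$color$data
    id <- prof$infrared$data
    rel <- prof$color$events[["release"]]
    occ <- prof$color$events[["occlusion_start"]]
    # oxygenation exceeds baseline within 10 min post-release
    expect_gte(cd$value[cd$time_min == rel + 10], 0)
    # hyperemic overshoot decays back toward baseline by 30 min
    peak <- max(cd$value[cd$time_min > rel])
    expect_lt(cd$value[cd$time_min == rel + 30], peak / 2)
    # infrared occlusion segment is monotone nonincreasing
    seg <- id$value[id$time_min >= occ & id$time_min <= rel]
    expect_true(all(diff(seg) <= 1e-9))
    # infrared recovery is monotone with no overshoot above baseline
    post <- id$value[id$time_min >= rel]
    expect_true(all(diff(post) >= -1e-9))
    expect_lte(max(post), id$value[1] + 1e-9)
  }
})

test_that("4.7 h arms stay below baseline temperature at 30 min post-release", {
  co <- generate_cohort(small_config(), seed = 3)
  for (i in seq_len(nrow(co$animals))) {
    aid <- co$animals$animal_id[i]
    prof <- generate_profiles(co, aid, noise = 0)
    id <- prof$infrared$data
    rel <- prof$infrared$events[["release"]]
    final <- id$value[id$time_min == rel + 30]
    baseline <- id$value[1]
    if (co$animals$duration_label[i] == "4.7") {
      expect_lt(final, baseline - 0.3)
    } else if (co$animals$group[i] != "sham") {
      expect_gt(final, baseline - 0.5)
    }
  }
})

test_that("tourniquet arms are more severe than matched occlusion arms", {
  co <- generate_cohort(cohort_config(), seed = 17)
  gmean <- function(col, grp) {
    mean(co$true_features[[col]][co$animals$group == grp])
  }
  # larger ischemic R-B drop and steeper reperfusion slope under tourniquet
  expect_gt(gmean("3CCD Slope Rpf", "tourniquet_3.5"),
            gmean("3CCD Slope Rpf", "occlusion_3.5"))
  expect_gt(gmean("3CCD Slope Rpf", "tourniquet_4.7"),
            gmean("3CCD Slope Rpf", "occlusion_4.7"))
})

test_that("lab trajectories peak on the quoted days and scale with severity", {
  co <- generate_cohort(small_config(), seed = 8)
  ids <- co$animals$animal_id
  sev <- co$animals$severity
  ck_scaled <- numeric(length(ids))
  for (i in seq_along(ids)) {
    labs <- generate_labs(co, ids[i], noise = 0)
    if (sev[i] > 0) {
      for (a in c("CK", "AST", "LDH")) {
        d <- labs[labs$analyte == a, ]
        expect_equal(d$timepoint_min[which.max(d$value)], 1440)
      }
      alt <- labs[labs$analyte == "ALT", ]
      expect_equal(alt$timepoint_min[which.max(alt$value)], 4320)
      co2 <- labs[labs$analyte == "CO2", ]
      nadir <- co2$timepoint_min[which.min(co2$value)]
      expect_lt(nadir, 1440)  # bicarbonate nadir before 24 h
    } else {
      # sham amplitudes stay in the baseline band
      expect_lt(max(labs$value[labs$analyte == "CK"]) / 800, 1.05)
    }
    # per-animal amplitude noise divided out: isolates the severity scaling
    ck_scaled[i] <- (max(labs$value[labs$analyte == "CK"]) / 800 - 1) /
      co$ground_truth$lab_amp[i]
  }
  # construction amplitude is strictly increasing in severity at noise 0
  agg <- tapply(ck_scaled, sev, mean)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) > 0))
})

test_that("recovery rates calibrate to the configured group probabilities", {
  cfg <- cohort_config(
    group_sizes = c(sham = 40, occlusion_3.5 = 160, tourniquet_3.5 = 160,
                    occlusion_4.7 = 160, tourniquet_4.7 = 160),
    simulate_exclusions = FALSE
  )
  co <- generate_cohort(cfg, seed = 20)
  frac <- function(lbl) {
    sel <- co$animals$duration_label == lbl
    mean(co$animals$recovered[sel])
  }
  n47 <- 320
  expect_lt(abs(frac("4.7") - 0.25), 3 * sqrt(0.25 * 0.75 / n47))
  expect_lt(abs(frac("3.5") - 0.75), 3 * sqrt(0.75 * 0.25 / 320))
  expect_gt(frac("sham"), 0.9)
})

test_that("outcome link strength increases with beta on the true score", {
  aucs <- vapply(c(0, 2, 6), function(b) {
    cfg <- cohort_config(
      group_sizes = c(sham = 0, occlusion_3.5 = 150, tourniquet_3.5 = 0,
                      occlusion_4.7 = 150, tourniquet_4.7 = 0),
      recovery_prob = c(sham = 0.5, "3.5" = 0.5, "4.7" = 0.5),
      beta = b, simulate_exclusions = FALSE
    )
    co <- generate_cohort(cfg, seed = 31)
    truth <- !co$animals$recovered  # positive class: did not recover
    score <- -(co$true_features[["IR Whole Leg Rpf5"]] +
                 100 * co$true_features[["3CCD PORH Slope Rpf5"]])
    roc_auc(scale(score)[, 1], truth)$auc
  }, numeric(1))
  # with equalized group rates, beta = 0 means no feature-outcome link
  expect_lt(abs(aucs[1] - 0.5), 0.08)
  expect_gt(aucs[2], aucs[1] + 0.05)
  expect_gt(aucs[3], aucs[2])
})

test_that("equipment-failure animals lose post-release color features", {
  co <- generate_cohort(cohort_config(), seed = 2)
  equip <- co$animals$animal_id[which(co$animals$exclusion_reason == "equipment_malfunction")]
  feats <- cohort_features(co)
  for (aid in equip) {
    row <- feats[feats$animal_id == aid, ]
    expect_true(all(is.na(row[, c("3CCD Slope Rpf", "3CCD Whole Leg Rpf10",
                                  "3CCD PORH Slope Rpf5")])))
    expect_false(is.na(row[["IR Whole Leg Rpf5"]]))
  }
})
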