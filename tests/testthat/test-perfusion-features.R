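test_that("landmarks: extrema, post values and missingness behave as specified", {
  # monotone-decreasing occlusion segment: minimum sits at release
  t <- seq(0, 40, by = 5)
  v <- c(0, 0, -2, -5, -9, -14, 6, 3, 1)  # occ 10, rel 25, overshoot at 30
  lm <- locate_landmarks(make_profile(t, v, occlusion_start = 10, release = 25))
  expect_equal(lm$max_ischemia$value, -14)
  expect_equal(lm$max_ischemia$time, 25)
  expect_equal(lm$max_reperfusion$value, 6)
  expect_equal(lm$max_reperfusion$time, 30)
  expect_equal(unname(lm$post[["rpf5"]]), 6)
  expect_equal(unname(lm$post[["rpf10"]]), 3)
  expect_true(is.na(lm$post[["rpf30"]]))  # profile truncated before release+30

  # overshoot peak at release+6 is the reperfusion maximum
  t2 <- c(0, 5, 10, 15, 20, 26, 30, 35)
  v2 <- c(0, 0, -4, -8, -10, 9, 5, 2)
  lm2 <- locate_landmarks(make_profile(t2, v2, occlusion_start = 8, release = 20))
  expect_equal(lm2$max_reperfusion$value, 9)
  expect_equal(lm2$max_reperfusion$time, 26)

  # last_pre_release variant uses the final sample at or before release
  v3 <- c(0, 0, -4, -12, -10, 9, 5, 2)
  lm3 <- locate_landmarks(make_profile(t2, v3, occlusion_start = 8, release = 20),
                          max_ischemia = "last_pre_release")
  expect_equal(lm3$max_ischemia$value, -10)
  expect_equal(lm3$max_ischemia$time, 20)
})

test_that("landmark extrema equal a brute-force scan over window samples", {
  set.seed(99)
  for (rep in 1:25) {
    t <- seq(0, 60, by = 5)
    v <- rnorm(length(t), 0, 5)
    occ <- 10; rel <- 30
    lm <- locate_landmarks(make_profile(t, v, occ, rel))
    in_occ <- t >= occ & t <= rel
    expect_equal(lm$max_ischemia$value, min(v[in_occ]))
    in_rpf <- t > rel & t <= rel + 10
    expect_equal(lm$max_reperfusion$value, max(v[in_rpf]))
    for (off in c(5, 10, 30)) {
      i <- which.min(abs(t - (rel + off)))
      expect_equal(unname(lm$post[[paste0("rpf", off)]]), v[i])
    }
  }
})

test_that("slope_of_reperfusion follows its defining arithmetic", {
  lm <- fake_landmarks(mi_val = -12, mi_time = 100, mr_val = 6, mr_time = 112,
                       release = 100)
  expect_equal(slope_of_reperfusion(lm), 1.5)   # 18 over 12 min
  lm_eq <- fake_landmarks(mi_val = 4, mi_time = 100, mr_val = 4, mr_time = 110,
                          release = 100)
  expect_equal(slope_of_reperfusion(lm_eq), 0)
  lm_ir <- fake_landmarks(mi_val = 90, mi_time = 200, mr_val = 99, mr_time = 230,
                          release = 200)
  expect_equal(slope_of_reperfusion(lm_ir), 0.3)  # 9 degF over 30 min
  lm_zero <- fake_landmarks(mi_val = 0, mi_time = 100, mr_val = 1, mr_time = 100,
                            release = 100)
  expect_error(slope_of_reperfusion(lm_zero), class = "limbperf_validation_error")
  expect_equal(slope_of_reperfusion(lm, duration = "fixed_10"), 1.8)
})

test_that("slope_of_porh measures overshoot decay with the right sign", {
  lm <- fake_landmarks(mi_val = -10, mi_time = 95, mr_val = 8, mr_time = 102,
                       post = c(rpf5 = NA, rpf10 = 0, rpf30 = -1), release = 100)
  expect_equal(slope_of_porh(lm, 10), -1)       # (0 - 8) / (110 - 102)
  lm_flat <- fake_landmarks(mi_val = -10, mi_time = 95, mr_val = 8, mr_time = 102,
                            post = c(rpf5 = NA, rpf10 = 8, rpf30 = 8), release = 100)
  expect_equal(slope_of_porh(lm_flat, 10), 0)
  # offset at or before the reperfusion maximum is undefined
  lm_late <- fake_landmarks(mi_val = -10, mi_time = 95, mr_val = 8, mr_time = 106,
                            post = c(rpf5 = 2, rpf10 = 1, rpf30 = 0), release = 100)
  expect_error(slope_of_porh(lm_late, 5), class = "limbperf_validation_error")
  # a decaying hyperemic overshoot always yields a negative slope
  lm_decay <- fake_landmarks(mi_val = -10, mi_time = 95, mr_val = 9, mr_time = 102.5,
                             post = c(rpf5 = 7, rpf10 = 4, rpf30 = 1), release = 100)
  expect_lt(slope_of_porh(lm_decay, 5), 0)
  expect_lt(slope_of_porh(lm_decay, 10), 0)
})

test_that("slope features are shift-invariant and scale-equivariant", {
  t <- c(0, 5, 10, 15, 20, 22.5, 25, 30, 40, 50)
  v <- c(0, 0, -3, -7, -11, 8, 6, 4, 1, 0.5)
  p0 <- make_profile(t, v, occlusion_start = 8, release = 20)
  s0 <- c(slope_of_reperfusion(locate_landmarks(p0)),
          slope_of_porh(locate_landmarks(p0), 5),
          slope_of_porh(locate_landmarks(p0), 30))
  for (shift in c(-20, 13)) {
    ps <- make_profile(t, v + shift, occlusion_start = 8, release = 20)
    ss <- c(slope_of_reperfusion(locate_landmarks(ps)),
            slope_of_porh(locate_landmarks(ps), 5),
            slope_of_porh(locate_landmarks(ps), 30))
    expect_equal(ss, s0)
  }
  for (a in c(0.5, 3)) {
    pa <- make_profile(t, a * v, occlusion_start = 8, release = 20)
    sa <- c(slope_of_reperfusion(locate_landmarks(pa)),
            slope_of_porh(locate_landmarks(pa), 5),
            slope_of_porh(locate_landmarks(pa), 30))
    expect_equal(sa, a * s0)
  }
})

test_that("piecewise-linear construction slopes are recovered exactly", {
  # built with reperfusion slope 2 %/min over 2.5 min, decay slope -0.4 %/min
  rel <- 20
  t <- c(0, 5, 10, 15, 20, 22.5, 25, 30, 40, 50)
  peak <- -8 + 2 * 2.5
  v <- c(0, 0, -4, -8, -8, peak, peak - 0.4 * 2.5, peak - 0.4 * 7.5,
         peak - 0.4 * 17.5, peak - 0.4 * 27.5)
  lm <- locate_landmarks(make_profile(t, v, occlusion_start = 8, release = rel))
  expect_equal(slope_of_reperfusion(lm), 2)
  expect_equal(slope_of_porh(lm, 5), -0.4)
  expect_equal(slope_of_porh(lm, 10), -0.4)
  expect_equal(slope_of_porh(lm, 30), -0.4)
})

test_that("build_feature_vector emits the 12 named columns and handles absence", {
  t <- c(0, 5, 10, 15, 20, 22.5, 25, 30, 40, 50)
  v <- c(0, 0, -3, -7, -11, 8, 6, 4, 1, 0.5)
  col <- make_profile(t, v, occlusion_start = 8, release = 20)
  irv <- c(101, 101, 100, 99, 98, 99.8, 99.5, 99.2, 99.0, 98.8)
  ir <- make_profile(t, irv, occlusion_start = 8, release = 20,
                     modality = "infrared", unit = "F")
  fv <- build_feature_vector(color = col, infrared = ir)
  expect_named(fv, limbperf:::imaging_feature_names())
  # constructed IR peak at release+2.5 makes every IR feature defined
  expect_false(anyNA(fv))

  ir_only <- build_feature_vector(infrared = ir)
  expect_true(all(is.na(ir_only[, grep("^3CCD", names(ir_only))])))
  expect_false(anyNA(ir_only[, grep("^IR", names(ir_only))]))
  expect_error(build_feature_vector(), class = "limbperf_validation_error")
})
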