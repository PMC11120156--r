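test_that("generator ground truth matches its stated world", {
  # at 100/min successive bottoms are 0.6 s apart
  sess <- fixture_session(rate_bpm = 100, n_phases = 1,
                          presses_per_phase = 10)
  expect_equal(diff(sess$truth$bottom_times), rep(0.6, 9))
  expect_equal(sess$truth$period_s, 0.6)

  # amplitude is depth times calibration by construction; at 100/min and
  # 30 fps the bottoms fall exactly on the sampling grid
  sess <- fixture_session(true_depth_cm = 5, rate_px_per_cm = 10,
                          rate_bpm = 100, fps = 30,
                          n_phases = 1, presses_per_phase = 5)
  expect_equal(sess$truth$amplitude_px, 50)
  wy <- lowest_wrist_y(sess$trace)
  expect_equal(max(wy) - min(wy), 50)

  # press count and bottoms inside CPR intervals
  sess <- fixture_session(n_phases = 3, presses_per_phase = 7)
  expect_length(sess$truth$bottom_times, 21)
  cpr <- sess$truth$phases[sess$truth$phases$label == "CPR", ]
  inside <- vapply(sess$truth$bottom_times, function(b)
    any(cpr$start <= b & b <= cpr$end), logical(1))
  expect_true(all(inside))
})

test_that("generator is reproducible and dropout only zeroes confidences", {
  spec <- synthetic_spec(noise_px_sd = 1.2, dropout_prob = 0.2,
                         n_phases = 1, presses_per_phase = 5, seed = 99)
  a <- generate_session(spec)
  b <- generate_session(spec)
  expect_identical(as.data.frame(a$trace), as.data.frame(b$trace))

  clean <- generate_session(synthetic_spec(noise_px_sd = 1.2,
                                           dropout_prob = 0,
                                           n_phases = 1,
                                           presses_per_phase = 5,
                                           seed = 99))
  coord_cols <- grep("_[xy]$", names(as.data.frame(a$trace)), value = TRUE)
  expect_identical(as.data.frame(a$trace)[, coord_cols],
                   as.data.frame(clean$trace)[, coord_cols])
  conf <- as.matrix(as.data.frame(a$trace)[, paste0(KP_NAMES, "_c")])
  expect_true(any(conf == 0))
  expect_true(all(conf %in% c(0, 0.9)))
})

test_that("spec bounds are enforced at construction", {
  expect_error(synthetic_spec(true_depth_cm = 0), "true_depth_cm")
  expect_error(synthetic_spec(elbow_angle_deg = 181), "elbow_angle_deg")
  expect_error(synthetic_spec(dropout_prob = 1), "dropout_prob")
  expect_error(synthetic_spec(recoil_fraction = 0), "recoil_fraction")
})

test_that("arm_geometry realises the requested elbow angle", {
  # closed forms: straight arm is collinear, 90 degrees is perpendicular
  g <- arm_geometry(180, 100, c(50, 300))
  expect_equal(angle_oracle(g$shoulder, g$elbow, g$wrist), 180)
  cross <- (g$wrist - g$elbow)[1] * (g$shoulder - g$elbow)[2] -
    (g$wrist - g$elbow)[2] * (g$shoulder - g$elbow)[1]
  expect_lt(abs(cross), 1e-9)

  g <- arm_geometry(90, 80, c(0, 0))
  expect_equal(sum((g$shoulder - g$elbow) * (g$wrist - g$elbow)), 0,
               tolerance = 1e-9)

  # law of cosines: c^2 = a^2 + b^2 - 2ab cos(theta)
  g <- arm_geometry(120, 100, c(10, 20))
  expect_equal(sqrt(sum((g$shoulder - g$wrist)^2)), 100 * sqrt(3),
               tolerance = 1e-9)

  # recomputed angle matches the request to 1e-6 degrees over a sweep
  for (ang in c(1, 17.3, 45, 88.8, 120, 165, 179.5, 180)) {
    for (side in c("left", "right")) {
      g <- arm_geometry(ang, 77, c(-5, 12), side)
      expect_equal(elbow_angle(g$shoulder, g$elbow, g$wrist), ang,
                   tolerance = 1e-6)
    }
  }
  expect_error(arm_geometry(0, 100), "angle")
  expect_error(arm_geometry(200, 100), "angle")
})

test_that("waveform period and recoil behave as specified", {
  spec <- synthetic_spec(rate_bpm = 117, n_phases = 1,
                         presses_per_phase = 4)
  expect_equal(spec$rate_bpm / 60 * 60 / spec$rate_bpm, 1)  # sanity
  sess <- generate_session(spec)
  expect_equal(diff(sess$truth$bottom_times),
               rep(60 / 117, 3), tolerance = 1e-12)

  # partial recoil keeps bottoms but raises inter-press tops
  part <- generate_session(synthetic_spec(recoil_fraction = 0.6,
                                          n_phases = 1,
                                          presses_per_phase = 6,
                                          rate_bpm = 120, fps = 60))
  wy <- lowest_wrist_y(part$trace)
  h0 <- part$truth$initial_height_px
  amp <- part$truth$amplitude_px
  expect_equal(max(wy), h0 + amp, tolerance = amp * 0.01)
  # top between presses 3 and 4 sits well above rest height
  tt <- part$trace$t
  mid <- part$truth$bottom_times[3:4]
  sel <- tt > mid[1] & tt < mid[2]
  expect_gt(min(wy[sel]) - h0, 0.25 * amp)
})
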