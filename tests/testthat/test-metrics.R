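test_that("compression depth is linear displacement over calibration", {
  cal <- calibration(10)
  expect_equal(compression_depth(300, 250, cal), 5.0)
  expect_equal(compression_depth(250, 250, cal), 0)
  set.seed(3)
  for (k in 1:20) {
    d <- runif(1, 1, 60)
    expect_equal(compression_depth(250 + 2 * d, 250, cal),
                 2 * compression_depth(250 + d, 250, cal))
  }
  expect_error(compression_depth(240, 250, cal), "negative depth")
  expect_equal(calibration(ref_length_px = 150,
                           ref_length_cm = 15)$px_per_cm, 10)
  expect_error(calibration(-1), "positive")
})

test_that("compression frequency is 60 over the press time", {
  expect_equal(compression_frequency(0.6), 100)
  expect_equal(compression_frequency(0.5), 120)
  expect_equal(compression_frequency(1.0), 60)
  # involution with the defining relation
  for (f in c(30, 100, 117.3, 200))
    expect_equal(compression_frequency(60 / f), f)
  expect_error(compression_frequency(0), "positive")
  expect_error(compression_frequency(-0.5), "positive")
})

test_that("elbow angle matches the dot-product oracle", {
  expect_equal(elbow_angle(c(0, 0), c(0, 1), c(0, 2)), 180)
  expect_equal(elbow_angle(c(0, 1), c(0, 0), c(1, 0)), 90)
  expect_equal(elbow_angle(c(0, 0), c(4, 0), c(4, 3)), 90)

  set.seed(21)
  for (k in 1:10000) {
    A <- runif(2, -100, 100); B <- runif(2, -100, 100)
    C <- runif(2, -100, 100)
    if (sum((A - B)^2) < 1e-6 || sum((C - B)^2) < 1e-6) next
    ref <- angle_oracle(A, B, C)
    # near-collinear triples are degenerate for the acos oracle itself:
    # d(acos)/dx blows up, so its own rounding error exceeds 1e-9 degrees
    if (ref < 1e-3 || ref > 180 - 1e-3) next
    expect_lt(abs(elbow_angle(A, B, C) - ref), 1e-9)
  }
  expect_error(elbow_angle(c(1, 1), c(1, 1), c(2, 2)), "coincident")
})

test_that("elbow angle is invariant under rigid maps and A/C swap", {
  set.seed(22)
  for (k in 1:200) {
    A <- runif(2, -10, 10); B <- runif(2, -10, 10); C <- runif(2, -10, 10)
    if (sum((A - B)^2) < 1e-4 || sum((C - B)^2) < 1e-4) next
    base <- elbow_angle(A, B, C)
    expect_equal(elbow_angle(C, B, A), base, tolerance = 1e-9)

    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 10)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shift <- runif(2, -50, 50)
    tf <- function(p) as.vector(s * R %*% p + shift)
    expect_equal(elbow_angle(tf(A), tf(B), tf(C)), base,
                 tolerance = 1e-7)
  }
})

test_that("press classification bands follow the quality standard", {
  thr <- feedback_thresholds()
  cal <- calibration(10)
  tri_straight <- arm_geometry(175, 100, c(0, 300))
  tri_bent <- arm_geometry(160, 100, c(0, 300))
  as_tri <- function(g) list(A = g$shoulder, B = g$elbow, C = g$wrist)
  mk_press <- function(depth_cm, press_time) {
    data.frame(bottom_y = 250 + depth_cm * 10, initial_height = 250,
               press_time = press_time)
  }

  m <- classify_press(mk_press(4.2, 0.55), as_tri(tri_straight),
                      as_tri(tri_straight), cal, thr)
  expect_equal(m$depth_band, "shallow")
  expect_equal(m$posture, "normal")

  m <- classify_press(mk_press(5.5, 60 / 130), as_tri(tri_straight),
                      as_tri(tri_straight), cal, thr)
  expect_equal(m$freq_band, "fast")
  expect_equal(m$depth_band, "ok")

  # one bent elbow is enough for an abnormal posture
  m <- classify_press(mk_press(5.5, 0.55), as_tri(arm_geometry(170, 100)),
                      as_tri(tri_bent), cal, thr)
  expect_equal(m$posture, "abnormal")
  expect_equal(m$left_elbow_deg, 170, tolerance = 1e-6)
  expect_equal(m$right_elbow_deg, 160, tolerance = 1e-6)

  # band boundaries are compliant (closed ok intervals)
  for (d in c(5, 6))
    expect_equal(classify_press(mk_press(d, 0.55), as_tri(tri_straight),
                                as_tri(tri_straight), cal, thr)$depth_band,
                 "ok")
  for (bpm in c(100, 120))
    expect_equal(classify_press(mk_press(5.5, 60 / bpm),
                                as_tri(tri_straight), as_tri(tri_straight),
                                cal, thr)$freq_band,
                 "ok")
  expect_equal(band_depth <- classify_press(mk_press(6.01, 0.55),
                                            as_tri(tri_straight),
                                            as_tri(tri_straight),
                                            cal, thr)$depth_band, "deep")
})
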