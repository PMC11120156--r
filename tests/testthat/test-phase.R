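test_that("phase features separate motion from rest and are scale-free", {
  static <- trace_from_wrist_y(rep(250, 40))
  f <- phase_features(static)
  expect_equal(unname(f[c("var_norm", "delta_norm", "amp_norm")]),
               c(0, 0, 0))

  sess <- fixture_session(rate_bpm = 110, n_phases = 1,
                          presses_per_phase = 10)
  tr <- sess$trace
  cpr_idx <- which(tr$t >= 3 & tr$t < 4)
  pause_idx <- which(tr$t < 1)
  f_cpr <- phase_features(tr[cpr_idx, ])
  f_pause <- phase_features(tr[pause_idx, ])
  expect_gt(f_cpr[["amp_norm"]], f_pause[["amp_norm"]])

  # invariant under uniform scaling of all coordinates
  scaled <- as.data.frame(tr[cpr_idx, ])
  coord_cols <- grep("_[xy]$", names(scaled), value = TRUE)
  scaled[coord_cols] <- scaled[coord_cols] * 3.7
  expect_equal(phase_features(scaled), f_cpr, tolerance = 1e-12)

  gone <- as.data.frame(static)
  gone[paste0(KP_NAMES, "_c")] <- 0
  expect_error(phase_features(gone), "visible")
})

test_that("softmax probabilities are proper and consistent with labels", {
  p <- softmax(c(a = 2, b = 2))
  expect_equal(unname(p), c(0.5, 0.5))
  expect_equal(sum(softmax(c(100, -100, 3))), 1)
  expect_gt(softmax(c(50, -50))[1], 1 - 1e-9)

  res <- classify_phase(c(var_norm = 0.5, delta_norm = 0.1, amp_norm = 2))
  expect_equal(res$label, "CPR")
  expect_equal(sum(res$probabilities), 1, tolerance = 1e-9)
  expect_equal(res$label, names(which.max(res$probabilities)))
  expect_true(all(res$probabilities > 0))

  res <- classify_phase(c(var_norm = 0, delta_norm = 0, amp_norm = 0.01))
  expect_equal(res$label, "UNCPR")
})

test_that("heuristic fallback agrees with ground-truth phases at zero noise", {
  sess <- fixture_session(n_phases = 3, presses_per_phase = 8, seed = 4)
  w <- phase_windows(sess)
  pred <- vapply(seq_len(nrow(w$features)), function(i)
    classify_phase(w$features[i, ])$label, character(1))
  expect_gte(mean(pred == w$labels), 0.95)
})

test_that("trained classifier is reproducible and generalises", {
  sessions <- lapply(1:3, function(s)
    fixture_session(true_depth_cm = c(4.5, 5.5, 6.5)[s],
                    rate_bpm = c(95, 110, 125)[s],
                    elbow_angle_deg = c(168, 172, 176)[s],
                    n_phases = 2, presses_per_phase = 8,
                    noise_px_sd = 0.8, seed = 100 + s))
  w <- lapply(sessions, phase_windows)
  feats <- do.call(rbind, lapply(w, `[[`, "features"))
  labs <- do.call(c, lapply(w, `[[`, "labels"))
  expect_gte(length(labs), 90)

  set.seed(55)
  idx <- sample(length(labs))
  train <- idx[seq_len(floor(0.67 * length(idx)))]
  test <- setdiff(idx, train)

  m1 <- train_phase_classifier(feats[train, ], labs[train], seed = 9)
  m2 <- train_phase_classifier(feats[train, ], labs[train], seed = 9)
  pred <- function(m, X) vapply(seq_len(nrow(X)), function(i)
    classify_phase(X[i, ], m)$label, character(1))
  expect_identical(pred(m1, feats), pred(m2, feats))

  # separable training set is fit perfectly; held-out windows >= 90%
  expect_gte(mean(pred(m1, feats[train, ]) == labs[train]), 0.99)
  expect_gte(mean(pred(m1, feats[test, ]) == labs[test]), 0.90)

  expect_error(train_phase_classifier(feats[1:5, ],
                                      rep("CPR", 5)), "both classes")

  # JSON round trip preserves predictions
  path <- withr::local_tempfile(fileext = ".json")
  save_phase_model(m1, path)
  m3 <- load_phase_model(path)
  expect_identical(pred(m1, feats), pred(m3, feats))
})

test_that("cycle state machine counts transitions and terminates", {
  cfg <- cycle_config()
  st <- session_state()
  st <- update_cycle(st, "CPR", FALSE, cfg)
  expect_equal(st$cycle_count, 1L)           # UNCPR -> CPR opens cycle 1
  st <- update_cycle(st, "CPR", FALSE, cfg)
  expect_equal(st$cycle_count, 1L)           # CPR -> CPR unchanged
  st <- update_cycle(st, "UNCPR", FALSE, cfg)
  st <- update_cycle(st, "CPR", FALSE, cfg)
  expect_equal(st$cycle_count, 2L)

  # five full cycles then termination at the fifth phase exit
  st <- session_state()
  for (cyc in 1:5) {
    st <- update_cycle(st, "CPR", FALSE, cfg)
    for (p in 1:29) st <- update_cycle(st, "CPR", TRUE, cfg)
    st <- update_cycle(st, "UNCPR", FALSE, cfg)
  }
  expect_true(st$terminated)
  expect_equal(st$cycle_count, 5L)
  # further phases are ignored once terminated
  st2 <- update_cycle(st, "CPR", TRUE, cfg)
  expect_equal(st2$cycle_count, 5L)

  # press-count completion also terminates
  st <- session_state()
  for (cyc in 1:5) {
    st <- update_cycle(st, "CPR", FALSE, cfg)
    for (p in 1:30) st <- update_cycle(st, "CPR", TRUE, cfg)
    if (cyc < 5) st <- update_cycle(st, "UNCPR", FALSE, cfg)
  }
  expect_true(st$terminated)

  # cycle_count is non-decreasing under random label streams
  set.seed(6)
  st <- session_state()
  prev <- 0L
  for (k in 1:500) {
    st <- update_cycle(st, sample(c("CPR", "UNCPR"), 1),
                       runif(1) < 0.5, cfg)
    expect_gte(st$cycle_count, prev)
    prev <- st$cycle_count
  }
  expect_lte(st$cycle_count, cfg$max_cycles)
})
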