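# Shared fixtures: all synthetic, generated in code at test time.

# small noise-free session used by several tests
fixture_session <- function(..., seed = 1L) {
  generate_session(synthetic_spec(..., seed = seed))
}

# independent dot-product oracle for the elbow angle
angle_oracle <- function(A, B, C) {
  u <- A - B; v <- C - B
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# brute-force agreement oracles
mae_oracle <- function(ref, est) {
  s <- 0
  for (i in seq_along(ref)) s <- s + abs(ref[i] - est[i])
  s / length(ref)
}
acc_oracle <- function(ref, est, tol) {
  n_ok <- 0
  for (i in seq_along(ref)) if (abs(ref[i] - est[i]) <= tol)
    n_ok <- n_ok + 1
  100 * n_ok / length(ref)
}

# a minimal single-frame trace with controllable wrist rows
one_frame <- function(lw_y = 200, rw_y = 210, conf = 0.9, t = 0) {
  row <- list(t = t)
  for (nm in KP_NAMES) {
    row[[paste0(nm, "_x")]] <- 100
    row[[paste0(nm, "_y")]] <- 150
    row[[paste0(nm, "_c")]] <- conf
  }
  row$left_wrist_y <- lw_y
  row$right_wrist_y <- rw_y
  as.data.frame(row)
}

# trace from a raw wrist-y vector (all keypoints visible, rigid geometry)
trace_from_wrist_y <- function(wy, fps = 30) {
  n <- length(wy)
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    one_frame(lw_y = wy[i] - 3, rw_y = wy[i], t = (i - 1) / fps)))
  df$left_shoulder_y <- wy - 200
  df$right_shoulder_y <- wy - 200
  df$left_shoulder_x <- 120
  df$right_shoulder_x <- 200
  kp_trace(df)
}

# labelled phase-classifier windows sampled from a generated session
phase_windows <- function(sess, window_s = 1, step_s = 0.5) {
  tr <- sess$trace
  ph <- sess$truth$phases
  starts <- seq(tr$t[1], tr$t[nrow(tr)] - window_s, by = step_s)
  feats <- list(); labs <- character(0)
  for (s in starts) {
    inside <- which(ph$start <= s & ph$end >= s + window_s)
    if (length(inside) != 1L) next           # skip straddling windows
    idx <- which(tr$t >= s & tr$t < s + window_s)
    if (length(idx) < 2L) next
    f <- tryCatch(phase_features(tr[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(f)) next
    feats[[length(feats) + 1L]] <- f
    labs <- c(labs, ph$label[inside])
  }
  list(features = do.call(rbind, feats), labels = labs)
}
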