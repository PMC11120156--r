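#' Specification of a synthetic compression session
#'
#' The generator emulates the keypoint trace a mobile pose estimator would
#' produce while filming chest compressions: the wrist follows a raised
#' cosine (starting from rest height, matching a detector armed at rest),
#' descending `true_depth_cm * rate_px_per_cm` pixels per press at
#' `rate_bpm` compressions per minute, in `n_phases` blocks of
#' `presses_per_phase` compressions separated (and followed) by pauses of
#' `pause_s` seconds at rest. Shoulders and elbows are placed so the elbow
#' angle equals `elbow_angle_deg` throughout. Gaussian pixel noise and
#' keypoint dropout (confidence set to 0) are applied after the geometry.
#'
#' @param true_depth_cm ground-truth compression depth in cm (> 0).
#' @param rate_bpm ground-truth compression rate per minute (> 0).
#' @param rate_px_per_cm pixel-to-centimetre conversion rate (> 0).
#' @param elbow_angle_deg elbow extension angle in degrees, in (0, 180].
#' @param fps sampling rate in frames per second (> 0).
#' @param n_phases number of compression blocks (>= 1).
#' @param presses_per_phase compressions per block (>= 1); default 30, one
#'   standard cycle.
#' @param pause_s rest between blocks in seconds (>= 0).
#' @param lead_in_s rest before the first block (>= 0); gives the detector
#'   a resting baseline.
#' @param noise_px_sd standard deviation of Gaussian pixel noise (>= 0).
#' @param dropout_prob per-frame, per-keypoint probability of confidence 0,
#'   in \[0, 1).
#' @param recoil_fraction fraction of the press amplitude recovered at the
#'   top of each press; 1 (default) is full chest recoil.
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @param initial_height_px resting wrist y (pixels, image convention).
#' @param segment_px upper-arm/forearm segment length in pixels.
#' @param base_confidence confidence of non-dropped keypoints.
#' @return An object of class `cpr_synth_spec`.
#' @export
synthetic_spec <- function(true_depth_cm = 5.5, rate_bpm = 110,
                           rate_px_per_cm = 10, elbow_angle_deg = 172,
                           fps = 30, n_phases = 5, presses_per_phase = 30,
                           pause_s = 5, lead_in_s = 2, noise_px_sd = 0,
                           dropout_prob = 0, recoil_fraction = 1,
                           seed = 1L, initial_height_px = 250,
                           segment_px = 100, base_confidence = 0.9) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(true_depth_cm > 0, "true_depth_cm must be > 0")
  chk(rate_bpm > 0, "rate_bpm must be > 0")
  chk(rate_px_per_cm > 0, "rate_px_per_cm must be > 0")
  chk(elbow_angle_deg > 0 && elbow_angle_deg <= 180,
      "elbow_angle_deg must lie in (0, 180]")
  chk(fps > 0, "fps must be > 0")
  chk(n_phases >= 1, "n_phases must be >= 1")
  chk(presses_per_phase >= 1, "presses_per_phase must be >= 1")
  chk(pause_s >= 0, "pause_s must be >= 0")
  chk(lead_in_s >= 0, "lead_in_s must be >= 0")
  chk(noise_px_sd >= 0, "noise_px_sd must be >= 0")
  chk(dropout_prob >= 0 && dropout_prob < 1, "dropout_prob must be in [0, 1)")
  chk(recoil_fraction > 0 && recoil_fraction <= 1,
      "recoil_fraction must be in (0, 1]")
  structure(as.list(environment())[names(formals(synthetic_spec))],
            class = "cpr_synth_spec")
}

#' Arm geometry with a prescribed elbow angle
#'
#' Places shoulder and elbow relative to a wrist anchor so that the elbow
#' angle (at the elbow, between forearm and upper arm) equals `angle_deg`
#' exactly. The forearm is vertical (elbow directly above the wrist under
#' the image convention) and the shoulder leans toward `side`.
#'
#' @param angle_deg elbow angle in degrees, in (0, 180]; 180 is a straight
#'   (collinear) arm.
#' @param segment_px segment length in pixels, used for both forearm and
#'   upper arm (> 0).
#' @param wrist_anchor numeric `(x, y)` of the wrist in pixels.
#' @param side `"left"` or `"right"`: which way the shoulder leans.
#' @return List with numeric `(x, y)` elements `shoulder`, `elbow`, `wrist`.
#' @export
arm_geometry <- function(angle_deg, segment_px, wrist_anchor = c(0, 0),
                         side = c("right", "left")) {
  side <- match.arg(side)
  if (!is.finite(angle_deg) || angle_deg <= 0 || angle_deg > 180)
    stop("angle_deg must lie in (0, 180]", call. = FALSE)
  if (!is.finite(segment_px) || segment_px <= 0)
    stop("segment_px must be > 0", call. = FALSE)
  s <- if (side == "right") 1 else -1
  th <- angle_deg * pi / 180
  elbow <- c(wrist_anchor[1], wrist_anchor[2] - segment_px)
  shoulder <- elbow + segment_px * c(s * sin(th), cos(th))
  list(shoulder = shoulder, elbow = elbow, wrist = as.numeric(wrist_anchor))
}

# Analytic wrist-y waveform at phase-local times tt (>= 0): raised cosine
# from rest, optionally with partial recoil after the first descent.
synth_waveform <- function(tt, amplitude_px, period_s, recoil_fraction) {
  u <- (1 - cos(2 * pi * tt / period_s)) / 2
  if (recoil_fraction < 1) {
    floor_frac <- (1 - recoil_fraction) * pmin(1, 2 * tt / period_s)
    u <- floor_frac + (1 - floor_frac) * u
  }
  amplitude_px * u
}

#' Generate a synthetic compression session
#'
#' Builds the keypoint trace described by a [synthetic_spec()] together
#' with its ground truth: per-press bottom times and depths, CPR/UNCPR
#' phase intervals, and the constant elbow angle. Dropout only zeroes
#' confidences; coordinates are never altered by it.
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `trace` (a [kp_trace()]) and `truth` (list
#'   with `bottom_times`, `depth_cm`, `phases` data frame
#'   (`start`,`end`,`label`), `elbow_angle_deg`, `initial_height_px`,
#'   `amplitude_px`, `period_s`).
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "cpr_synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  period <- 60 / spec$rate_bpm
  phase_len <- spec$presses_per_phase * period
  amp <- spec$true_depth_cm * spec$rate_px_per_cm
  h0 <- spec$initial_height_px

  starts <- spec$lead_in_s + (seq_len(spec$n_phases) - 1) *
    (phase_len + spec$pause_s)
  ends <- starts + phase_len
  total <- ends[spec$n_phases] + max(spec$pause_s, 1)

  t <- seq(0, total, by = 1 / spec$fps)
  wy <- rep(h0, length(t))
  for (p in seq_len(spec$n_phases)) {
    idx <- t >= starts[p] & t < ends[p]
    wy[idx] <- h0 + synth_waveform(t[idx] - starts[p], amp, period,
                                   spec$recoil_fraction)
  }

  # hands stacked: right wrist carries the waveform and is the lower one
  cx <- 160
  rw_x <- cx + 2; lw_x <- cx - 2
  n <- length(t)
  geom_l <- arm_geometry(spec$elbow_angle_deg, spec$segment_px,
                         c(lw_x, 0), side = "left")
  geom_r <- arm_geometry(spec$elbow_angle_deg, spec$segment_px,
                         c(rw_x, 0), side = "right")
  frames <- data.frame(
    t = t,
    left_shoulder_x  = rep(geom_l$shoulder[1], n),
    left_shoulder_y  = wy - 3 + geom_l$shoulder[2],
    left_shoulder_c  = rep(spec$base_confidence, n),
    right_shoulder_x = rep(geom_r$shoulder[1], n),
    right_shoulder_y = wy + geom_r$shoulder[2],
    right_shoulder_c = rep(spec$base_confidence, n),
    left_elbow_x     = rep(geom_l$elbow[1], n),
    left_elbow_y     = wy - 3 + geom_l$elbow[2],
    left_elbow_c     = rep(spec$base_confidence, n),
    right_elbow_x    = rep(geom_r$elbow[1], n),
    right_elbow_y    = wy + geom_r$elbow[2],
    right_elbow_c    = rep(spec$base_confidence, n),
    left_wrist_x     = rep(lw_x, n),
    left_wrist_y     = wy - 3,
    left_wrist_c     = rep(spec$base_confidence, n),
    right_wrist_x    = rep(rw_x, n),
    right_wrist_y    = wy,
    right_wrist_c    = rep(spec$base_confidence, n)
  )

  if (spec$noise_px_sd > 0) {
    for (col in kp_cols()) {
      if (grepl("_c$", col)) next
      frames[[col]] <- frames[[col]] +
        stats::rnorm(n, sd = spec$noise_px_sd)
    }
  }
  if (spec$dropout_prob > 0) {
    for (nm in KP_NAMES) {
      drop <- stats::runif(n) < spec$dropout_prob
      frames[[paste0(nm, "_c")]][drop] <- 0
    }
  }

  bottoms <- as.vector(vapply(seq_len(spec$n_phases), function(p)
    starts[p] + (seq_len(spec$presses_per_phase) - 0.5) * period,
    numeric(spec$presses_per_phase)))

  pauses <- data.frame(start = c(0, ends), end = c(starts, total),
                       label = "UNCPR", stringsAsFactors = FALSE)
  pauses <- pauses[pauses$end > pauses$start, ]
  phases <- rbind(pauses,
                  data.frame(start = starts, end = ends, label = "CPR",
                             stringsAsFactors = FALSE))
  phases <- phases[order(phases$start), ]
  rownames(phases) <- NULL

  truth <- list(bottom_times = bottoms,
                depth_cm = rep(spec$true_depth_cm, length(bottoms)),
                phases = phases,
                elbow_angle_deg = spec$elbow_angle_deg,
                initial_height_px = h0,
                amplitude_px = amp,
                period_s = period)
  trace <- kp_trace(frames,
                    metadata = list(fps = spec$fps,
                                    px_per_cm = spec$rate_px_per_cm,
                                    source = "cprqa synthetic generator"))
  list(trace = trace, truth = truth)
}
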