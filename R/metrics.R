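#' Pixel-to-centimetre calibration
#'
#' Wrist displacement is measured in image pixels; depth feedback needs
#' centimetres. The conversion rate (pixels per centimetre) must be supplied
#' by the user, either directly or as a reference length visible in frame
#' (e.g. a manikin of known size).
#'
#' @param px_per_cm pixels per centimetre (> 0), or `NULL` to derive from a
#'   reference length.
#' @param ref_length_px,ref_length_cm a reference length in pixels and its
#'   known physical size in centimetres; used when `px_per_cm` is `NULL`.
#' @return An object of class `cpr_calibration`.
#' @export
calibration <- function(px_per_cm = NULL, ref_length_px = NULL,
                        ref_length_cm = NULL) {
  derived <- NULL
  if (is.null(px_per_cm)) {
    if (is.null(ref_length_px) || is.null(ref_length_cm))
      stop("supply px_per_cm, or both ref_length_px and ref_length_cm",
           call. = FALSE)
    px_per_cm <- ref_length_px / ref_length_cm
    derived <- sprintf("%g px / %g cm reference length",
                       ref_length_px, ref_length_cm)
  }
  if (!is.finite(px_per_cm) || px_per_cm <= 0)
    stop("px_per_cm must be a finite positive number", call. = FALSE)
  structure(list(px_per_cm = px_per_cm, derived_from = derived),
            class = "cpr_calibration")
}

#' Compression depth from wrist displacement
#'
#' Depth is the wrist's press-bottom displacement below its resting height,
#' divided by the calibration rate:
#' `depth_cm = (bottom_y - initial_height) / px_per_cm`.
#' Under the image convention the bottom has the *larger* pixel y.
#'
#' @param bottom_y wrist y at the press bottom (pixels).
#' @param initial_height resting wrist y before compression (pixels).
#' @param cal a [calibration()].
#' @return Depth in centimetres (vectorised).
#' @export
compression_depth <- function(bottom_y, initial_height, cal) {
  stopifnot(inherits(cal, "cpr_calibration"))
  if (any(bottom_y < initial_height))
    stop("bottom_y must not be above initial_height (y grows downward); ",
         "negative depth is impossible", call. = FALSE)
  (bottom_y - initial_height) / cal$px_per_cm
}

#' Compression frequency from press time
#'
#' One compression spanning `press_time_s` seconds bottom-to-bottom
#' corresponds to `60 / press_time_s` compressions per minute; e.g. a press
#' time of 0.6 s is 100 bpm, 0.5 s is 120 bpm.
#'
#' @param press_time_s bottom-to-bottom press time in seconds (> 0).
#' @return Frequency in compressions per minute (vectorised).
#' @export
compression_frequency <- function(press_time_s) {
  if (any(!is.finite(press_time_s)) || any(press_time_s <= 0))
    stop("press_time_s must be positive", call. = FALSE)
  60 / press_time_s
}

#' Elbow angle from shoulder, elbow and wrist points
#'
#' The elbow angle phi at point B (elbow) of the triple A (shoulder),
#' B (elbow), C (wrist) follows from the law of cosines,
#' `cos(phi) = (BC^2 + AB^2 - AC^2) / (2 * BC * AB)`,
#' inverted to the angle itself (the 165-degree posture threshold only
#' makes sense for phi, not its cosine). Since
#' `BC^2 + AB^2 - AC^2 = 2 (A-B).(C-B)` exactly, the angle is evaluated in
#' the numerically stable form `atan2(|u x v|, u.v)` with `u = A-B`,
#' `v = C-B`, which avoids the cancellation the squared-length ratio
#' suffers near collinear triples. A straight arm gives 180 degrees.
#'
#' @param A,B,C numeric length-2 vectors `(x, y)` in pixels, or n x 2
#'   matrices for vectorised use.
#' @return Angle(s) in degrees, in \[0, 180\].
#' @export
elbow_angle <- function(A, B, C) {
  A <- rbind(A); B <- rbind(B); C <- rbind(C)
  u <- A - B
  v <- C - B
  if (any(rowSums(u^2) == 0) || any(rowSums(v^2) == 0))
    stop("coincident points: elbow angle undefined", call. = FALSE)
  dot <- rowSums(u * v)
  crs <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  ang <- atan2(abs(crs), dot) * 180 / pi
  if (length(ang) == 1L) as.numeric(ang) else ang
}

#' Quality thresholds for feedback
#'
#' Defaults encode the high-quality CPR standard: compression depth between
#' 5 and 6 cm, rate between 100 and 120 per minute, and both elbows
#' extended beyond 165 degrees. Band membership uses closed "ok" intervals:
#' boundary values are compliant.
#'
#' @param depth_min_cm,depth_max_cm compliant depth band (cm).
#' @param freq_min_bpm,freq_max_bpm compliant rate band (per minute).
#' @param posture_min_deg minimum elbow extension angle (degrees); posture
#'   is normal only when *both* elbows exceed it.
#' @return An object of class `cpr_thresholds`.
#' @export
feedback_thresholds <- function(depth_min_cm = 5, depth_max_cm = 6,
                                freq_min_bpm = 100, freq_max_bpm = 120,
                                posture_min_deg = 165) {
  stopifnot(depth_min_cm < depth_max_cm, freq_min_bpm < freq_max_bpm)
  if (posture_min_deg <= 0 || posture_min_deg > 180)
    stop("posture_min_deg must lie in (0, 180]", call. = FALSE)
  structure(list(depth_min_cm = depth_min_cm, depth_max_cm = depth_max_cm,
                 freq_min_bpm = freq_min_bpm, freq_max_bpm = freq_max_bpm,
                 posture_min_deg = posture_min_deg),
            class = "cpr_thresholds")
}

band_depth <- function(depth_cm, thr) {
  ifelse(depth_cm < thr$depth_min_cm, "shallow",
         ifelse(depth_cm > thr$depth_max_cm, "deep", "ok"))
}

band_freq <- function(bpm, thr) {
  ifelse(bpm < thr$freq_min_bpm, "slow",
         ifelse(bpm > thr$freq_max_bpm, "fast", "ok"))
}

band_posture <- function(left_deg, right_deg, thr) {
  ifelse(left_deg > thr$posture_min_deg & right_deg > thr$posture_min_deg,
         "normal", "abnormal")
}

#' Per-press quality metrics
#'
#' Combines a detected press with its elbow geometry at the press bottom
#' into depth, frequency and posture metrics plus their band
#' classifications (shallow/ok/deep, slow/ok/fast, normal/abnormal).
#'
#' @param press one row of the [detect_presses()] result (needs `bottom_y`,
#'   `initial_height`, `press_time`).
#' @param tri_left,tri_right lists with points `A` (shoulder), `B` (elbow),
#'   `C` (wrist), each a numeric `(x, y)` pair, for the left/right arm.
#' @param cal a [calibration()].
#' @param thr a [feedback_thresholds()].
#' @return One-row data frame of class `cpr_press_metrics`.
#' @export
classify_press <- function(press, tri_left, tri_right, cal,
                           thr = feedback_thresholds()) {
  depth <- compression_depth(press$bottom_y, press$initial_height, cal)
  bpm <- compression_frequency(press$press_time)
  la <- elbow_angle(tri_left$A, tri_left$B, tri_left$C)
  ra <- elbow_angle(tri_right$A, tri_right$B, tri_right$C)
  out <- data.frame(depth_cm = depth, frequency_bpm = bpm,
                    left_elbow_deg = la, right_elbow_deg = ra,
                    depth_band = band_depth(depth, thr),
                    freq_band = band_freq(bpm, thr),
                    posture = band_posture(la, ra, thr),
                    stringsAsFactors = FALSE)
  class(out) <- c("cpr_press_metrics", "data.frame")
  out
}
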