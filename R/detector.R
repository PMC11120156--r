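#' Press-detector configuration
#'
#' The detector is a three-state machine over the lowest-wrist-y signal.
#' State 0 records the resting height until the wrist starts moving down;
#' state 1 tracks the descent to the press bottom and, when the excursion
#' from the resting height exceeds `start_threshold_px`, anchors the press
#' start at the bottom; state 2 waits for the wrist to return within
#' `return_threshold_px` of the resting height (full chest recoil) and
#' emits one press event per subsequent bottom that returns within
#' `return_threshold_px` of the previous bottom, the press time being the
#' bottom-to-bottom interval.
#'
#' @param start_threshold_px minimum excursion (pixels) from the resting
#'   height for a descent to count as a press; default 15.5.
#' @param return_threshold_px recoil/return tolerance in pixels; default 5.
#' @param min_confidence presence-gate threshold; frames failing
#'   [person_present()] reset the machine to state 0.
#' @param hysteresis_px minimum y reversal (pixels) for a direction change,
#'   suppressing jitter flip-flops; default 1.
#' @param timeout_s bottoms further apart than this re-anchor instead of
#'   emitting, so no press event spans a pause; default 3 s.
#' @param smooth_window odd moving-average window applied to the wrist-y
#'   signal before detection; 1 disables (default). Use 3 for noisy
#'   keypoint backends.
#' @param refine_bottoms logical; refine each bottom's time and y by a
#'   local parabolic (three-point quadratic) fit around the sampled
#'   extreme, removing frame-quantisation error. Default `TRUE`.
#' @param px_per_cm,reference_px_per_cm if both given, the two pixel
#'   thresholds are rescaled by `px_per_cm / reference_px_per_cm`; the
#'   defaults (15.5 and 5) are resolution-dependent constants.
#' @return An object of class `cpr_detector_config`.
#' @export
detector_config <- function(start_threshold_px = 15.5,
                            return_threshold_px = 5,
                            min_confidence = 0.3,
                            hysteresis_px = 1,
                            timeout_s = 3,
                            smooth_window = 1,
                            refine_bottoms = TRUE,
                            px_per_cm = NULL,
                            reference_px_per_cm = NULL) {
  if (!is.null(px_per_cm) && !is.null(reference_px_per_cm)) {
    f <- px_per_cm / reference_px_per_cm
    start_threshold_px <- start_threshold_px * f
    return_threshold_px <- return_threshold_px * f
  }
  stopifnot(start_threshold_px > 0, return_threshold_px > 0,
            start_threshold_px > return_threshold_px,
            hysteresis_px >= 0, timeout_s > 0,
            smooth_window >= 1, smooth_window %% 2 == 1)
  structure(list(start_threshold_px = start_threshold_px,
                 return_threshold_px = return_threshold_px,
                 min_confidence = min_confidence,
                 hysteresis_px = hysteresis_px,
                 timeout_s = timeout_s,
                 smooth_window = smooth_window,
                 refine_bottoms = refine_bottoms),
            class = "cpr_detector_config")
}

#' Fresh detector state
#'
#' @return A list representing the machine at state 0 with no history.
#' @seealso [detector_step()]
#' @export
detector_state <- function() {
  list(state = 0L, dir = 0L,
       ext_max = -Inf, ext_max_t = NA_real_, ext_max_i = NA_integer_,
       ext_min = Inf, ext_min_t = NA_real_,
       init_sum = 0, init_n = 0L, initial_height = NA_real_,
       wrist_y1 = NA_real_, start_time = NA_real_,
       start_frame = NA_integer_,
       ready = FALSE, wrist_y2 = NA_real_, last_t = -Inf)
}

#' Advance the press detector by one frame
#'
#' Feeds one (time, wrist-y) sample through the three-state machine (see
#' [detector_config()] for the semantics). Direction changes are detected
#' with hysteresis; the machine re-arms after every emission so a session
#' yields one event per press.
#'
#' @param st detector state from [detector_state()] or a previous step.
#' @param t timestamp in seconds, strictly greater than the previous one.
#' @param wrist_y lowest wrist y in pixels; `NA` skips the frame with a
#'   warning.
#' @param cfg a [detector_config()].
#' @param frame_index optional row index carried into emitted events.
#' @return List with `state` (the new machine state) and `event` (`NULL`,
#'   or a one-row data frame with `start_time`, `end_time`, `press_time`,
#'   `bottom_y`, `initial_height`, `bottom_frame`, `start_frame`).
#' @export
detector_step <- function(st, t, wrist_y, cfg, frame_index = NA_integer_) {
  if (!is.finite(t) || t <= st$last_t)
    stop("timestamps passed to detector_step must be strictly increasing",
         call. = FALSE)
  if (!is.finite(wrist_y)) {
    warning("non-finite wrist_y at t=", t, "; frame skipped", call. = FALSE)
    st$last_t <- t
    return(list(state = st, event = NULL))
  }
  st$last_t <- t
  y <- wrist_y
  hyst <- cfg$hysteresis_px
  event <- NULL

  # --- extreme tracking -------------------------------------------------
  if (st$dir >= 0L && y > st$ext_max) {       # descending (or unknown)
    st$ext_max <- y; st$ext_max_t <- t; st$ext_max_i <- frame_index
  }
  if (st$dir <= 0L && y < st$ext_min) {       # ascending (or unknown)
    st$ext_min <- y; st$ext_min_t <- t
  }

  turn <- NULL                                 # "top" or "bottom"
  if (st$dir <= 0L && y > st$ext_min + hyst) {
    turn <- "top"                              # was ascending; now descends
    top_y <- st$ext_min; top_t <- st$ext_min_t
    st$dir <- 1L
    st$ext_max <- y; st$ext_max_t <- t; st$ext_max_i <- frame_index
  } else if (st$dir >= 0L && y < st$ext_max - hyst) {
    turn <- "bottom"                           # was descending; now ascends
    bot_y <- st$ext_max; bot_t <- st$ext_max_t; bot_i <- st$ext_max_i
    st$dir <- -1L
    st$ext_min <- y; st$ext_min_t <- t
  }

  # --- state machine ----------------------------------------------------
  if (st$state == 0L) {
    if (!is.null(turn) && turn == "top" || st$dir == 1L) {
      # downward motion begins: freeze initialHeight (mean of rest samples)
      st$initial_height <- if (st$init_n > 0L) st$init_sum / st$init_n else y
      st$state <- 1L
    } else {
      st$init_sum <- st$init_sum + y
      st$init_n <- st$init_n + 1L
    }
  } else if (st$state == 1L) {
    if (!is.null(turn) && turn == "bottom") {
      if (abs(st$initial_height - bot_y) > cfg$start_threshold_px) {
        st$wrist_y1 <- bot_y
        st$start_time <- bot_t
        st$start_frame <- bot_i
        st$ready <- FALSE
        st$state <- 2L
      } else {
        # sub-threshold dip: back to rest tracking
        st$state <- 0L
        st$init_sum <- y; st$init_n <- 1L
      }
    }
  } else {                                     # state 2
    if (!st$ready && abs(y - st$initial_height) < cfg$return_threshold_px)
      st$ready <- TRUE
    if (!is.null(turn)) {
      if (turn == "top") {
        st$wrist_y2 <- top_y                   # recoil top
      } else if (abs(st$initial_height - bot_y) > cfg$start_threshold_px) {
        dt <- bot_t - st$start_time
        if (st$ready && abs(st$wrist_y1 - bot_y) < cfg$return_threshold_px &&
            dt <= cfg$timeout_s && dt > 0) {
          event <- data.frame(start_time = st$start_time, end_time = bot_t,
                              press_time = dt, bottom_y = bot_y,
                              initial_height = st$initial_height,
                              bottom_frame = bot_i,
                              start_frame = st$start_frame)
        }
        # re-anchor at this bottom whether or not an event was emitted
        st$wrist_y1 <- bot_y
        st$start_time <- bot_t
        st$start_frame <- bot_i
        st$ready <- FALSE
      }
    }
  }
  list(state = st, event = event)
}

moving_average <- function(y, w) {
  if (w <= 1L) return(y)
  k <- (w - 1L) %/% 2L
  n <- length(y)
  out <- y
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Three-point parabolic refinement of a sampled extreme: returns the vertex
# (t*, y*) of the quadratic through (t,y) at i-1, i, i+1, with the time
# shift clamped to one frame interval. Falls back to the sample itself at
# trace edges or degenerate (non-concave) neighbourhoods.
refine_extreme <- function(t, y, i) {
  n <- length(t)
  if (i <= 1L || i >= n) return(c(t[i], y[i]))
  tt <- t[(i - 1L):(i + 1L)] - t[i]
  yy <- y[(i - 1L):(i + 1L)]
  fit <- try(stats::lm.fit(cbind(1, tt, tt^2), yy), silent = TRUE)
  if (inherits(fit, "try-error")) return(c(t[i], y[i]))
  a <- fit$coefficients[3]; b <- fit$coefficients[2]; c0 <- fit$coefficients[1]
  if (!is.finite(a) || a == 0) return(c(t[i], y[i]))
  shift <- -b / (2 * a)
  lim <- max(t[i] - t[i - 1L], t[i + 1L] - t[i])
  if (!is.finite(shift) || abs(shift) > lim) return(c(t[i], y[i]))
  c(t[i] + shift, c0 + b * shift + a * shift^2)
}

#' Detect compressions in a keypoint trace
#'
#' Batch driver for [detector_step()]: runs the lowest-wrist-y signal of a
#' trace through the three-state machine. Frames failing the presence gate
#' reset the machine to state 0 (a stale resting height is unsafe after an
#' occlusion). With `refine_bottoms` (default) each press bottom's time and
#' y are refined by a local parabolic fit before press times and depths are
#' derived, removing the frame-rate quantisation of the sampled extreme.
#'
#' @param trace a [kp_trace()].
#' @param cfg a [detector_config()].
#' @return Data frame of class `cpr_presses`, one row per detected press,
#'   ordered by `start_time`: columns `start_time`, `end_time`,
#'   `press_time` (s), `bottom_y`, `initial_height` (px), `bottom_frame`
#'   (row index of the press bottom). Zero rows when nothing is detected.
#' @export
detect_presses <- function(trace, cfg = detector_config()) {
  stopifnot(inherits(trace, "kp_trace"))
  y_raw <- lowest_wrist_y(trace)
  y <- moving_average(y_raw, cfg$smooth_window)
  t <- trace$t
  present <- person_present(trace, cfg$min_confidence)

  st <- detector_state()
  events <- list()
  for (i in seq_along(t)) {
    if (!present[i]) {
      st <- detector_state()
      st$last_t <- t[i]
      next
    }
    res <- detector_step(st, t[i], y[i], cfg, frame_index = i)
    st <- res$state
    if (!is.null(res$event)) events[[length(events) + 1L]] <- res$event
  }
  if (length(events) == 0L) {
    out <- data.frame(start_time = numeric(0), end_time = numeric(0),
                      press_time = numeric(0), bottom_y = numeric(0),
                      initial_height = numeric(0),
                      bottom_frame = integer(0))
    class(out) <- c("cpr_presses", "data.frame")
    return(out)
  }
  ev <- do.call(rbind, events)

  # refinement runs on the raw signal: the smoother is for robust state
  # transitions only and attenuates the true press amplitude
  if (isTRUE(cfg$refine_bottoms)) {
    ref <- function(i) refine_extreme(t, y_raw, i)
    for (r in seq_len(nrow(ev))) {
      rs <- ref(ev$start_frame[r])
      re <- ref(ev$bottom_frame[r])
      ev$start_time[r] <- rs[1]
      ev$end_time[r] <- re[1]
      ev$bottom_y[r] <- re[2]
      ev$press_time[r] <- re[1] - rs[1]
    }
    ev <- ev[ev$press_time > 0, , drop = FALSE]
  }
  ev$start_frame <- NULL
  ev <- ev[order(ev$start_time), ]
  rownames(ev) <- NULL
  class(ev) <- c("cpr_presses", "data.frame")
  ev
}
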