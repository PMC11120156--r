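#' Feedback message catalog
#'
#' Stable event codes with configurable display strings. The slow/fast
#' prompts have two common phrasings ("Pressing too slow" vs. "Please
#' press faster"); the codes are what downstream consumers should match
#' on, the messages are presentation only.
#'
#' @param ... named overrides, e.g. `TOO_SLOW = "Please press faster"`.
#' @return Named character vector keyed by event code.
#' @export
message_catalog <- function(...) {
  msgs <- c(MISSING = "Missing",
            NEXT_CYCLE = "Next cycle",
            TOO_SHALLOW = "Pressing too shallow",
            TOO_DEEP = "Pressing too deep",
            TOO_SLOW = "Pressing too slow",
            TOO_FAST = "Pressing too fast",
            POSE_ABNORMAL = "Abnormal compression pose",
            SESSION_END = "Detection ended")
  over <- c(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(msgs))
    if (length(bad) > 0)
      stop("unknown event code(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    msgs[names(over)] <- over
  }
  msgs
}

feedback_event <- function(timestamp, code, value = NA_real_,
                           catalog = message_catalog()) {
  data.frame(timestamp = timestamp, code = code, value = value,
             message = unname(catalog[code]), stringsAsFactors = FALSE)
}

elbow_triple_at <- function(trace, i, side) {
  pre <- paste0(side, "_")
  conf <- c(trace[[paste0(pre, "shoulder_c")]][i],
            trace[[paste0(pre, "elbow_c")]][i],
            trace[[paste0(pre, "wrist_c")]][i])
  if (any(conf <= 0)) return(NULL)
  list(A = c(trace[[paste0(pre, "shoulder_x")]][i],
             trace[[paste0(pre, "shoulder_y")]][i]),
       B = c(trace[[paste0(pre, "elbow_x")]][i],
             trace[[paste0(pre, "elbow_y")]][i]),
       C = c(trace[[paste0(pre, "wrist_x")]][i],
             trace[[paste0(pre, "wrist_y")]][i]))
}

# Sliding-window phase labels: windows of cycle$window_s with 50% overlap;
# windows with too few usable frames are UNCPR. Returns a data frame of
# window end times and labels, in time order.
phase_timeline <- function(trace, cycle, phase_model, amp_threshold) {
  t <- trace$t
  step <- cycle$window_s / 2
  starts <- seq(t[1], max(t[1], t[length(t)] - cycle$window_s), by = step)
  labs <- character(length(starts))
  ends <- numeric(length(starts))
  for (k in seq_along(starts)) {
    idx <- which(t >= starts[k] & t < starts[k] + cycle$window_s)
    ends[k] <- starts[k] + cycle$window_s
    labs[k] <- if (length(idx) < 2L) "UNCPR" else {
      f <- tryCatch(phase_features(trace[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(f)) "UNCPR" else
        classify_phase(f, phase_model, amp_threshold)$label
    }
  }
  data.frame(time = ends, label = labs, stringsAsFactors = FALSE)
}

#' Run a full compression-assessment session
#'
#' Single orchestrated pass over a keypoint trace: presence gating (with
#' MISSING events at each occlusion onset), CPR/UNCPR phase classification
#' on sliding windows, cycle counting with termination after `max_cycles`
#' completed cycles, press detection, per-press depth/frequency/posture
#' metrics, and coded feedback events. Deterministic for fixed inputs and
#' configuration.
#'
#' @param trace a [kp_trace()].
#' @param cal a [calibration()]; depth feedback is impossible without one.
#' @param thresholds a [feedback_thresholds()].
#' @param detector a [detector_config()].
#' @param cycle a [cycle_config()].
#' @param phase_model optional trained [train_phase_classifier()] model;
#'   default `NULL` uses the deterministic amplitude-threshold fallback.
#' @param amp_threshold fallback CPR amplitude threshold (shoulder-widths).
#' @param catalog a [message_catalog()].
#' @return An object of class `cpr_session`: list with `presses` (per-press
#'   metrics data frame), `events` (feedback events data frame),
#'   `cycles_completed`, `terminated`, `summary` (see
#'   [summary.cpr_session()]), plus the configuration used and the wrist
#'   trajectory for plotting.
#' @export
run_session <- function(trace, cal,
                        thresholds = feedback_thresholds(),
                        detector = detector_config(),
                        cycle = cycle_config(),
                        phase_model = NULL,
                        amp_threshold = 0.5,
                        catalog = message_catalog()) {
  stopifnot(inherits(trace, "kp_trace"))
  if (!inherits(cal, "cpr_calibration"))
    stop("run_session needs a calibration(); supply px_per_cm or a ",
         "reference length so wrist pixels can be converted to cm",
         call. = FALSE)

  present <- person_present(trace, detector$min_confidence)
  presses <- detect_presses(trace, detector)
  timeline <- phase_timeline(trace, cycle, phase_model, amp_threshold)

  # merge press-completion and window-label events in time order
  agenda <- data.frame(time = timeline$time, kind = "phase",
                       idx = seq_len(nrow(timeline)),
                       stringsAsFactors = FALSE)
  if (nrow(presses) > 0L)
    agenda <- rbind(agenda,
                    data.frame(time = presses$end_time, kind = "press",
                               idx = seq_len(nrow(presses)),
                               stringsAsFactors = FALSE))
  agenda <- agenda[order(agenda$time, agenda$kind), , drop = FALSE]

  events <- list()
  add_event <- function(ts, code, value = NA_real_)
    events[[length(events) + 1L]] <<- feedback_event(ts, code, value,
                                                     catalog)

  # MISSING at each occlusion onset
  onsets <- which(!present & c(TRUE, present[-length(present)]))
  for (i in onsets) add_event(trace$t[i], "MISSING")

  st <- session_state()
  metrics_rows <- list()
  end_time <- NA_real_
  for (r in seq_len(nrow(agenda))) {
    tm <- agenda$time[r]
    if (agenda$kind[r] == "phase") {
      lab <- timeline$label[agenda$idx[r]]
      if (st$previous_phase == "CPR" && lab == "UNCPR" && !st$terminated)
        add_event(tm, "NEXT_CYCLE", st$cycle_count)
      st <- update_cycle(st, lab, FALSE, cycle)
    } else {
      p <- presses[agenda$idx[r], , drop = FALSE]
      st <- update_cycle(st, st$previous_phase, TRUE, cycle)
      tl <- elbow_triple_at(trace, p$bottom_frame, "left")
      tr <- elbow_triple_at(trace, p$bottom_frame, "right")
      depth <- compression_depth(p$bottom_y, p$initial_height, cal)
      bpm <- compression_frequency(p$press_time)
      la <- if (is.null(tl)) NA_real_ else elbow_angle(tl$A, tl$B, tl$C)
      ra <- if (is.null(tr)) NA_real_ else elbow_angle(tr$A, tr$B, tr$C)
      posture <- if (is.na(la) || is.na(ra)) NA_character_ else
        band_posture(la, ra, thresholds)
      db <- band_depth(depth, thresholds)
      fb <- band_freq(bpm, thresholds)
      metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
        time = tm, cycle = st$cycle_count, depth_cm = depth,
        frequency_bpm = bpm, left_elbow_deg = la, right_elbow_deg = ra,
        depth_band = db, freq_band = fb, posture = posture,
        stringsAsFactors = FALSE)
      if (db == "shallow") add_event(tm, "TOO_SHALLOW", depth)
      if (db == "deep") add_event(tm, "TOO_DEEP", depth)
      if (fb == "slow") add_event(tm, "TOO_SLOW", bpm)
      if (fb == "fast") add_event(tm, "TOO_FAST", bpm)
      if (!is.na(posture) && posture == "abnormal")
        add_event(tm, "POSE_ABNORMAL", min(la, ra))
    }
    if (st$terminated) { end_time <- tm; break }
  }

  if (is.na(end_time)) end_time <- trace$t[nrow(trace)]
  add_event(end_time, "SESSION_END", st$cycle_count)

  press_df <- if (length(metrics_rows) > 0) {
    do.call(rbind, metrics_rows)
  } else {
    data.frame(time = numeric(0), cycle = integer(0),
               depth_cm = numeric(0), frequency_bpm = numeric(0),
               left_elbow_deg = numeric(0), right_elbow_deg = numeric(0),
               depth_band = character(0), freq_band = character(0),
               posture = character(0), stringsAsFactors = FALSE)
  }
  ev_df <- do.call(rbind, events)
  ev_df <- ev_df[ev_df$timestamp <= end_time, , drop = FALSE]
  ev_df <- ev_df[order(ev_df$timestamp), , drop = FALSE]
  rownames(ev_df) <- NULL

  report <- structure(
    list(presses = press_df, events = ev_df,
         cycles_completed = st$cycle_count,
         terminated = st$terminated,
         end_time = end_time,
         config = list(thresholds = thresholds, detector = detector,
                       cycle = cycle, calibration = cal),
         trajectory = data.frame(t = trace$t,
                                 wrist_y = lowest_wrist_y(trace),
                                 present = present)),
    class = "cpr_session")
  report$summary <- summarize_session(report)
  report
}

#' Summarise a session report
#'
#' Whole-session and per-cycle mean depth, mean frequency, and the
#' percentage of presses compliant on each criterion (depth in band, rate
#' in band, posture normal).
#'
#' @param report a `cpr_session` from [run_session()].
#' @return Data frame, one row per cycle plus a final `session` row, with
#'   columns `n_presses`, `mean_depth_cm`, `mean_frequency_bpm` and the
#'   three compliance percentages. Zero presses give an all-`NA` row with
#'   a warning.
#' @export
summarize_session <- function(report) {
  p <- report$presses
  one <- function(q, label) {
    if (nrow(q) == 0L)
      return(data.frame(scope = label, n_presses = 0L,
                        mean_depth_cm = NA_real_,
                        mean_frequency_bpm = NA_real_,
                        depth_ok_pct = NA_real_, freq_ok_pct = NA_real_,
                        posture_ok_pct = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(scope = label, n_presses = nrow(q),
               mean_depth_cm = mean(q$depth_cm),
               mean_frequency_bpm = mean(q$frequency_bpm),
               depth_ok_pct = 100 * mean(q$depth_band == "ok"),
               freq_ok_pct = 100 * mean(q$freq_band == "ok"),
               posture_ok_pct = 100 * mean(q$posture == "normal",
                                           na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  if (nrow(p) == 0L) {
    warning("session contains no detected presses; summary is empty",
            call. = FALSE)
    return(one(p, "session"))
  }
  rows <- lapply(sort(unique(p$cycle)), function(cy)
    one(p[p$cycle == cy, , drop = FALSE], paste0("cycle_", cy)))
  out <- rbind(do.call(rbind, rows), one(p, "session"))
  rownames(out) <- NULL
  out
}

#' @export
summary.cpr_session <- function(object, ...) object$summary

#' @export
print.cpr_session <- function(x, ...) {
  s <- x$summary[x$summary$scope == "session", ]
  cat("Compression session report\n")
  cat(sprintf("  cycles completed: %d%s\n", x$cycles_completed,
              if (x$terminated) " (terminated by protocol)" else ""))
  cat(sprintf("  presses analysed: %d\n", s$n_presses))
  if (s$n_presses > 0) {
    cat(sprintf("  mean depth:       %.2f cm (%.0f%% in band)\n",
                s$mean_depth_cm, s$depth_ok_pct))
    cat(sprintf("  mean frequency:   %.1f /min (%.0f%% in band)\n",
                s$mean_frequency_bpm, s$freq_ok_pct))
    cat(sprintf("  posture normal:   %.0f%% of presses\n",
                s$posture_ok_pct))
  }
  cat(sprintf("  feedback events:  %d\n", nrow(x$events)))
  invisible(x)
}

#' Plot a session's wrist trajectory and feedback
#'
#' Base-graphics plot of the lowest-wrist-y signal (image convention:
#' the axis is reversed so "down" in the scene is down in the plot) with
#' detected press times marked and the compliant depth band shaded.
#'
#' @param x a `cpr_session`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cpr_session <- function(x, ...) {
  tr <- x$trajectory
  graphics::plot(tr$t, tr$wrist_y, type = "l", ylim = rev(range(tr$wrist_y)),
                 xlab = "time (s)", ylab = "lowest wrist y (px, image)", ...)
  cal <- x$config$calibration
  thr <- x$config$thresholds
  if (nrow(x$presses) > 0) {
    h0 <- stats::median(tr$wrist_y[tr$t < x$presses$time[1]])
    graphics::abline(h = h0 + thr$depth_min_cm * cal$px_per_cm,
                     lty = 3, col = "darkgreen")
    graphics::abline(h = h0 + thr$depth_max_cm * cal$px_per_cm,
                     lty = 3, col = "darkgreen")
    graphics::points(x$presses$time,
                     stats::approx(tr$t, tr$wrist_y, x$presses$time)$y,
                     col = "red", pch = 16, cex = 0.6)
  }
  graphics::abline(v = x$end_time, lty = 2, col = "grey40")
  invisible(x)
}
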