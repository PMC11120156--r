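#' Assemble a full application configuration
#'
#' Bundles the component configurations. Defaults are the protocol
#' constants: press thresholds 15.5 / 5 px, compliant depth 5-6 cm, rate
#' 100-120 per minute, elbow extension > 165 degrees, 30 presses per
#' cycle, 5 cycles per session.
#'
#' @param detector a [detector_config()].
#' @param thresholds a [feedback_thresholds()].
#' @param cycle a [cycle_config()].
#' @param calibration optional [calibration()].
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return An object of class `cpr_config`.
#' @export
app_config <- function(detector = detector_config(),
                       thresholds = feedback_thresholds(),
                       cycle = cycle_config(),
                       calibration = NULL,
                       log_level = "info") {
  stopifnot(inherits(detector, "cpr_detector_config"),
            inherits(thresholds, "cpr_thresholds"),
            inherits(cycle, "cpr_cycle_config"))
  if (!log_level %in% c("debug", "info", "warn", "error"))
    stop("log_level must be one of debug/info/warn/error", call. = FALSE)
  if (!is.null(calibration) && !inherits(calibration, "cpr_calibration"))
    stop("calibration must come from calibration()", call. = FALSE)
  structure(list(detector = detector, thresholds = thresholds,
                 cycle = cycle, calibration = calibration,
                 log_level = log_level),
            class = "cpr_config")
}

config_sections <- list(
  detector = c("start_threshold_px", "return_threshold_px",
               "min_confidence", "hysteresis_px", "timeout_s",
               "smooth_window", "refine_bottoms"),
  thresholds = c("depth_min_cm", "depth_max_cm", "freq_min_bpm",
                 "freq_max_bpm", "posture_min_deg"),
  cycle = c("presses_per_cycle", "max_cycles", "window_s"),
  calibration = c("px_per_cm", "ref_length_px", "ref_length_cm")
)

#' Load a YAML configuration
#'
#' Absent keys take the protocol defaults (an empty file yields the full
#' default configuration); unknown sections or keys are rejected; values
#' are validated by the component constructors, which name the offending
#' key and bound.
#'
#' @param path path to a YAML file with optional sections `detector:`,
#'   `thresholds:`, `cycle:`, `calibration:`, `log_level:`.
#' @return A validated [app_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(names(config_sections), "log_level")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  build <- function(section, ctor) {
    vals <- raw[[section]]
    if (is.null(vals)) vals <- list()
    bad <- setdiff(names(vals), config_sections[[section]])
    if (length(bad) > 0)
      stop("unknown key(s) in '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    do.call(ctor, vals)
  }
  cal <- if (is.null(raw$calibration)) NULL else
    build("calibration", calibration)
  app_config(detector = build("detector", detector_config),
             thresholds = build("thresholds", feedback_thresholds),
             cycle = build("cycle", cycle_config),
             calibration = cal,
             log_level = if (is.null(raw$log_level)) "info" else
               raw$log_level)
}

#' Save a configuration as YAML
#'
#' Round-trips with [load_config()].
#'
#' @param config an [app_config()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "cpr_config"))
  out <- list(
    detector = unclass(config$detector)[config_sections$detector],
    thresholds = unclass(config$thresholds),
    cycle = unclass(config$cycle),
    log_level = config$log_level)
  if (!is.null(config$calibration))
    out$calibration <- list(px_per_cm = config$calibration$px_per_cm)
  yaml::write_yaml(out, path)
  invisible(path)
}
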