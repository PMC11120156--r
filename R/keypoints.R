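#' Required upper-limb keypoint names
#'
#' The six keypoints the pipeline evaluates: left/right shoulder, elbow and
#' wrist of the standard 17-point pose skeleton. The "arm" points shown on
#' typical mobile pose overlays are mapped to the shoulder keypoints.
#'
#' @format Character vector of length 6.
#' @export
KP_NAMES <- c("left_shoulder", "right_shoulder",
              "left_elbow",    "right_elbow",
              "left_wrist",    "right_wrist")

kp_cols <- function(names = KP_NAMES) {
  as.vector(t(outer(names, c("x", "y", "c"), paste, sep = "_")))
}

#' Construct a keypoint trace
#'
#' A keypoint trace is a data frame with one row per video frame: a timestamp
#' column `t` (seconds, strictly increasing) and, for each of the six
#' required keypoints, columns `<name>_x`, `<name>_y` (image pixels) and
#' `<name>_c` (detection confidence in \[0, 1\]).
#'
#' Coordinates follow the image convention: y increases downward, so a
#' *larger* y pixel value is a *physically lower* position. All depth logic
#' in the package depends on this convention.
#'
#' @param frames data frame with column `t` and the 18 keypoint columns.
#' @param metadata optional named list (fps hint, source, calibration, ...).
#' @return An object of class `kp_trace` (a validated data frame).
#' @export
kp_trace <- function(frames, metadata = list()) {
  stopifnot(is.data.frame(frames))
  frames <- as.data.frame(frames)
  need <- c("t", kp_cols())
  missing_cols <- setdiff(need, names(frames))
  if (length(missing_cols) > 0L)
    stop("trace is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  frames <- frames[, need]
  if (nrow(frames) == 0L)
    stop("trace must contain at least one frame", call. = FALSE)
  if (any(!is.finite(frames$t)))
    stop("timestamps must be finite", call. = FALSE)
  if (nrow(frames) > 1L && any(diff(frames$t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  conf <- as.matrix(frames[, paste0(KP_NAMES, "_c")])
  if (any(!is.finite(conf)) || any(conf < 0) || any(conf > 1))
    stop("keypoint confidences must lie in [0, 1]", call. = FALSE)
  xy <- as.matrix(frames[, c(paste0(KP_NAMES, "_x"), paste0(KP_NAMES, "_y"))])
  if (any(!is.finite(xy)))
    stop("keypoint coordinates must be finite", call. = FALSE)
  structure(frames, metadata = metadata, class = c("kp_trace", "data.frame"))
}

#' @export
print.kp_trace <- function(x, ...) {
  cat(sprintf("<kp_trace> %d frames, %.2f s (%s)\n", nrow(x),
              x$t[nrow(x)] - x$t[1],
              paste0(names(attr(x, "metadata")), collapse = ", ")))
  invisible(x)
}

#' Lowest wrist position of each frame
#'
#' Returns `max(left_wrist_y, right_wrist_y)` per frame. Under the image
#' convention (y grows downward) the maximum pixel y is the physically
#' lowest wrist, the position relevant for compression depth.
#'
#' @param trace a `kp_trace` or any data frame with the wrist columns.
#' @return Numeric vector, one value per frame.
#' @export
lowest_wrist_y <- function(trace) {
  for (col in c("left_wrist_y", "right_wrist_y"))
    if (is.null(trace[[col]]))
      stop("missing wrist keypoint column: ", col, call. = FALSE)
  pmax(trace$left_wrist_y, trace$right_wrist_y)
}

#' Person-presence gate
#'
#' A frame counts as "person present" when all six required keypoints are
#' detected with confidence at least `min_confidence`. Frames failing the
#' gate trigger a MISSING feedback event and reset the press detector.
#'
#' @param trace a `kp_trace`.
#' @param min_confidence confidence threshold in \[0, 1\]; default 0.3, the
#'   common operating point of mobile pose estimators.
#' @return Logical vector, one value per frame.
#' @export
person_present <- function(trace, min_confidence = 0.3) {
  conf <- as.matrix(as.data.frame(trace)[, paste0(KP_NAMES, "_c")])
  apply(conf >= min_confidence, 1L, all)
}

#' Read a keypoint trace from disk
#'
#' Two plain-text dialects are supported. `csv`: header
#' `t,left_shoulder_x,left_shoulder_y,left_shoulder_c,...` (six keypoints x
#' three columns, in `KP_NAMES` order). `jsonl`: one JSON object per line,
#' `{"t": <s>, "kp": {"left_shoulder": {"x":..,"y":..,"c":..}, ...}}`.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"jsonl"`; default guessed from the extension.
#' @return A `kp_trace`.
#' @export
read_trace <- function(path, dialect = c("auto", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "csv") {
    df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                   error = function(e) stop("malformed CSV trace '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    if (nrow(df) == 0L) stop("empty trace file: ", path, call. = FALSE)
    bad <- which(!stats::complete.cases(df))
    if (length(bad) > 0L)
      stop("malformed row at line ", bad[1] + 1L, " of ", path, call. = FALSE)
    kp_trace(df, metadata = list(source = path))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty trace file: ", path, call. = FALSE)
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("malformed JSON at line ", i,
                                               " of ", path, call. = FALSE))
      if (is.null(obj$t) || is.null(obj$kp))
        stop("malformed JSON at line ", i, " of ", path,
             ": needs fields 't' and 'kp'", call. = FALSE)
      row <- list(t = obj$t)
      for (nm in KP_NAMES) {
        k <- obj$kp[[nm]]
        if (is.null(k))
          stop("missing keypoint '", nm, "' at line ", i, " of ", path,
               call. = FALSE)
        row[[paste0(nm, "_x")]] <- k$x
        row[[paste0(nm, "_y")]] <- k$y
        row[[paste0(nm, "_c")]] <- k$c
      }
      rows[[i]] <- as.data.frame(row)
    }
    kp_trace(do.call(rbind, rows), metadata = list(source = path))
  }
}

#' Write a keypoint trace to disk
#'
#' @param trace a `kp_trace`.
#' @param path output file path.
#' @param dialect `"csv"` or `"jsonl"` (see [read_trace()] for the formats);
#'   default guessed from the extension.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path, dialect = c("auto", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  df <- as.data.frame(trace)[, c("t", kp_cols())]
  if (dialect == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      kp <- list()
      for (nm in KP_NAMES)
        kp[[nm]] <- list(x = df[[paste0(nm, "_x")]][i],
                         y = df[[paste0(nm, "_y")]][i],
                         c = df[[paste0(nm, "_c")]][i])
      writeLines(jsonlite::toJSON(list(t = df$t[i], kp = kp),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
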