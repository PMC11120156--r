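#' Cycle-tracking configuration
#'
#' A compression cycle is a block of compressions followed by a pause for
#' checks; the standard protocol is 30 compressions per cycle and 5 cycles
#' per session, after which detection ends.
#'
#' @param presses_per_cycle compressions per cycle; default 30.
#' @param max_cycles cycles per session; default 5.
#' @param window_s phase-classifier window length in seconds; default 1.0,
#'   which spans at least one compression at any compliant rate (period
#'   >= 0.5 s). Windows slide with 50% overlap.
#' @return An object of class `cpr_cycle_config`.
#' @export
cycle_config <- function(presses_per_cycle = 30, max_cycles = 5,
                         window_s = 1.0) {
  stopifnot(presses_per_cycle >= 1, max_cycles >= 1, window_s > 0)
  structure(list(presses_per_cycle = presses_per_cycle,
                 max_cycles = max_cycles, window_s = window_s),
            class = "cpr_cycle_config")
}

#' Motion features of a keypoint window
#'
#' Summarises a short window of frames into a fixed-length feature vector
#' for CPR/UNCPR phase classification: wrist-y variance, mean absolute
#' frame-to-frame wrist-y delta, and peak-to-peak wrist-y amplitude, all
#' normalised by the mean shoulder-to-shoulder distance so the features are
#' invariant to uniform scaling of the image. Frames whose wrist or
#' shoulder keypoints have zero confidence are excluded.
#'
#' @param window a `kp_trace` or data frame slice of consecutive frames.
#' @return Named numeric vector `c(var_norm, delta_norm, amp_norm)`.
#' @export
phase_features <- function(window) {
  w <- as.data.frame(window)
  usable <- w$left_wrist_c > 0 & w$right_wrist_c > 0 &
    w$left_shoulder_c > 0 & w$right_shoulder_c > 0
  w <- w[usable, , drop = FALSE]
  if (nrow(w) < 2L)
    stop("phase_features needs at least two frames with visible wrists ",
         "and shoulders", call. = FALSE)
  wy <- lowest_wrist_y(w)
  sw <- mean(sqrt((w$left_shoulder_x - w$right_shoulder_x)^2 +
                  (w$left_shoulder_y - w$right_shoulder_y)^2))
  if (!is.finite(sw) || sw <= 0)
    stop("degenerate shoulder geometry in window", call. = FALSE)
  c(var_norm = stats::var(wy) / sw^2,
    delta_norm = mean(abs(diff(wy))) / sw,
    amp_norm = (max(wy) - min(wy)) / sw)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Classify a window as CPR or UNCPR
#'
#' With a trained model (see [train_phase_classifier()]), computes softmax
#' class probabilities from the model's logits. Without one, a
#' deterministic amplitude-threshold fallback is used: the window is CPR
#' when its normalised peak-to-peak amplitude exceeds `amp_threshold`
#' shoulder-widths, with probabilities given by a logistic squash of the
#' margin (so the pipeline works with zero training).
#'
#' @param features a [phase_features()] vector.
#' @param model a `cpr_phase_model`, or `NULL` for the heuristic fallback.
#' @param amp_threshold heuristic CPR threshold on `amp_norm`; default 0.5.
#' @return List with `label` (`"CPR"` or `"UNCPR"`) and `probabilities`
#'   (named numeric summing to 1).
#' @export
classify_phase <- function(features, model = NULL, amp_threshold = 0.5) {
  if (is.null(model)) {
    z <- 10 * (features[["amp_norm"]] - amp_threshold)
    p <- softmax(c(CPR = z, UNCPR = -z))
  } else {
    stopifnot(inherits(model, "cpr_phase_model"))
    p <- softmax(phase_model_logits(model, features))
  }
  list(label = names(p)[which.max(p)], probabilities = p)
}

phase_model_logits <- function(model, features) {
  x <- (as.numeric(features) - model$center) / model$scale
  h <- tanh(model$W1 %*% x + model$b1)
  z <- as.numeric(model$W2 %*% h + model$b2)
  names(z) <- model$classes
  z
}

#' Train the CPR/UNCPR phase classifier
#'
#' Fits a small feed-forward network (one tanh hidden layer, softmax
#' output) on labelled window features by BFGS minimisation of the
#' cross-entropy with a light L2 penalty. Deterministic given `seed`.
#'
#' @param features numeric matrix, one row per window (columns as produced
#'   by [phase_features()]).
#' @param labels character vector of `"CPR"`/`"UNCPR"`, one per row.
#' @param hidden hidden-layer width; default 8.
#' @param seed integer seed for weight initialisation.
#' @param maxit BFGS iteration cap.
#' @return An object of class `cpr_phase_model`.
#' @export
train_phase_classifier <- function(features, labels, hidden = 8,
                                   seed = 1L, maxit = 300) {
  features <- as.matrix(features)
  classes <- c("CPR", "UNCPR")
  if (!all(labels %in% classes))
    stop("labels must be 'CPR' or 'UNCPR'", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  if (min(table(labels)) < 2L)
    stop("need at least two examples per class", call. = FALSE)

  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0] <- 1
  X <- sweep(sweep(features, 2, center), 2, scale, "/")
  Y <- outer(labels, classes, "==") * 1       # n x 2 one-hot
  n <- nrow(X); d <- ncol(X); h <- hidden

  unpack <- function(p) {
    i <- 0
    W1 <- matrix(p[i + seq_len(h * d)], h, d); i <- i + h * d
    b1 <- p[i + seq_len(h)]; i <- i + h
    W2 <- matrix(p[i + seq_len(2 * h)], 2, h); i <- i + 2 * h
    b2 <- p[i + seq_len(2)]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  lambda <- 1e-4
  fwd <- function(p) {
    w <- unpack(p)
    H <- tanh(X %*% t(w$W1) + matrix(w$b1, n, h, byrow = TRUE))
    Z <- H %*% t(w$W2) + matrix(w$b2, n, 2, byrow = TRUE)
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    list(w = w, H = H, P = P)
  }
  loss <- function(p) {
    f <- fwd(p)
    -sum(Y * log(pmax(f$P, 1e-12))) / n + lambda * sum(p^2)
  }
  grad <- function(p) {
    f <- fwd(p)
    dZ <- (f$P - Y) / n                        # n x 2
    gW2 <- t(dZ) %*% f$H
    gb2 <- colSums(dZ)
    dH <- dZ %*% f$w$W2 * (1 - f$H^2)          # n x h
    gW1 <- t(dH) %*% X
    gb1 <- colSums(dH)
    c(as.vector(gW1), gb1, as.vector(gW2), gb2) + 2 * lambda * p
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  p0 <- stats::rnorm(h * d + h + 2 * h + 2, sd = 0.5)
  opt <- stats::optim(p0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  w <- unpack(opt$par)
  structure(list(version = "1", hidden = h, classes = classes,
                 feature_names = colnames(features),
                 center = center, scale = scale,
                 W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 final_loss = opt$value),
            class = "cpr_phase_model")
}

#' Save / load a phase-classifier model as versioned JSON
#'
#' @param model a `cpr_phase_model`.
#' @param path file path for the JSON serialisation.
#' @return `load_phase_model` returns the model; `save_phase_model`
#'   invisibly returns `path`.
#' @export
save_phase_model <- function(model, path) {
  stopifnot(inherits(model, "cpr_phase_model"))
  obj <- unclass(model)
  obj$W1 <- as.vector(model$W1); obj$W2 <- as.vector(model$W2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_phase_model
#' @export
load_phase_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$W1 <- matrix(obj$W1, obj$hidden, length(obj$center))
  obj$W2 <- matrix(obj$W2, 2, obj$hidden)
  structure(obj, class = "cpr_phase_model")
}

#' Advance the session cycle state
#'
#' Increments the cycle count on each UNCPR-to-CPR transition (the first
#' onset of compressions counts as cycle 1), counts presses within the
#' current cycle, and terminates the session once `max_cycles` cycles have
#' run and the final cycle's compressions are complete — either the press
#' count reaches `presses_per_cycle` or the phase exits to UNCPR.
#'
#' @param state session state list (`cycle_count`, `presses_in_cycle`,
#'   `previous_phase`, `terminated`); see [session_state()].
#' @param phase current phase label, `"CPR"` or `"UNCPR"`.
#' @param press_emitted logical: did a press event complete at this step?
#' @param cfg a [cycle_config()].
#' @return The updated session state.
#' @export
update_cycle <- function(state, phase, press_emitted = FALSE,
                         cfg = cycle_config()) {
  if (state$terminated) return(state)
  if (state$previous_phase == "UNCPR" && phase == "CPR") {
    state$cycle_count <- state$cycle_count + 1L
    state$presses_in_cycle <- 0L
  }
  if (press_emitted)
    state$presses_in_cycle <- state$presses_in_cycle + 1L
  if (state$cycle_count >= cfg$max_cycles &&
      (state$presses_in_cycle >= cfg$presses_per_cycle ||
       (state$previous_phase == "CPR" && phase == "UNCPR")))
    state$terminated <- TRUE
  state$previous_phase <- phase
  state
}

#' Fresh session cycle state
#'
#' The session starts in the UNCPR phase with zero cycles, so the first
#' CPR onset opens cycle 1.
#'
#' @return A session-state list.
#' @export
session_state <- function() {
  list(cycle_count = 0L, presses_in_cycle = 0L,
       previous_phase = "UNCPR", terminated = FALSE)
}
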