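#' Paired depth series
#'
#' Index-aligned per-press compression depths from a reference device
#' (e.g. a sensor-instrumented manikin) and from this system, for
#' agreement analysis.
#'
#' @param reference,estimated numeric vectors of depths in cm, equal
#'   length, all values >= 0.
#' @return An object of class `cpr_paired_depths`.
#' @export
paired_depths <- function(reference, estimated) {
  reference <- as.numeric(reference)
  estimated <- as.numeric(estimated)
  if (length(reference) != length(estimated))
    stop("reference and estimated series must have equal length ",
         "(align them first, e.g. with align_presses())", call. = FALSE)
  if (length(reference) == 0L)
    stop("paired series must be non-empty", call. = FALSE)
  if (any(!is.finite(reference)) || any(!is.finite(estimated)) ||
      any(reference < 0) || any(estimated < 0))
    stop("depths must be finite and non-negative", call. = FALSE)
  structure(list(reference = reference, estimated = estimated),
            class = "cpr_paired_depths")
}

#' Align reference and estimated presses by bottom time
#'
#' Matches each estimated press to the nearest reference press whose
#' bottom time lies within `window_s`, one-to-one and greedily by
#' increasing time gap. Unmatched presses on either side are reported but
#' excluded from the paired series.
#'
#' @param reference,estimated data frames with columns `bottom_time_s` and
#'   `depth_cm`.
#' @param window_s maximum allowed bottom-time gap for a match; default
#'   0.3 s (below half a compliant press period, so neighbours cannot be
#'   confused).
#' @return List with `pairs` (a [paired_depths()]), `matches` (index data
#'   frame), `unmatched_reference`, `unmatched_estimated`.
#' @export
align_presses <- function(reference, estimated, window_s = 0.3) {
  stopifnot(all(c("bottom_time_s", "depth_cm") %in% names(reference)),
            all(c("bottom_time_s", "depth_cm") %in% names(estimated)))
  cand <- expand.grid(i = seq_len(nrow(reference)),
                      j = seq_len(nrow(estimated)))
  cand$gap <- abs(reference$bottom_time_s[cand$i] -
                  estimated$bottom_time_s[cand$j])
  cand <- cand[cand$gap <= window_s, , drop = FALSE]
  cand <- cand[order(cand$gap), , drop = FALSE]
  used_i <- logical(nrow(reference)); used_j <- logical(nrow(estimated))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_i[i] && !used_j[j]) {
      keep[r] <- TRUE; used_i[i] <- TRUE; used_j[j] <- TRUE
    }
  }
  m <- cand[keep, c("i", "j", "gap"), drop = FALSE]
  m <- m[order(m$i), , drop = FALSE]
  rownames(m) <- NULL
  if (nrow(m) == 0L)
    stop("no reference/estimated press pairs within ", window_s, " s",
         call. = FALSE)
  list(pairs = paired_depths(reference$depth_cm[m$i],
                             estimated$depth_cm[m$j]),
       matches = m,
       unmatched_reference = which(!used_i),
       unmatched_estimated = which(!used_j))
}

#' Mean absolute error between paired depth series
#'
#' @param pairs a [paired_depths()].
#' @return MAE in cm.
#' @export
mean_absolute_error <- function(pairs) {
  stopifnot(inherits(pairs, "cpr_paired_depths"))
  mean(abs(pairs$reference - pairs$estimated))
}

#' Tolerance accuracy of paired depth series
#'
#' Percentage of presses whose absolute depth error is at most `tol_cm`;
#' an error exactly at the tolerance counts as accurate.
#'
#' @param pairs a [paired_depths()].
#' @param tol_cm tolerance in cm; default 0.5.
#' @return Accuracy in percent, in \[0, 100\].
#' @export
tolerance_accuracy <- function(pairs, tol_cm = 0.5) {
  stopifnot(inherits(pairs, "cpr_paired_depths"), tol_cm >= 0)
  100 * mean(abs(pairs$reference - pairs$estimated) <= tol_cm)
}

#' Paired test on depth differences
#'
#' Two-sided paired test on per-press differences (reference minus
#' estimated). The default is the paired t-test, the standard choice for
#' paired continuous agreement; a Wilcoxon signed-rank option is provided.
#' Identical series (zero-variance differences) are degenerate: the test
#' is undefined and p is reported as 1 with a warning.
#'
#' @param pairs a [paired_depths()].
#' @param method `"t"` or `"wilcoxon"`.
#' @return List with `p_value`, `statistic`, `method`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_depth_test <- function(pairs, method = c("t", "wilcoxon")) {
  stopifnot(inherits(pairs, "cpr_paired_depths"))
  method <- match.arg(method)
  d <- pairs$reference - pairs$estimated
  if (length(d) < 2L)
    stop("paired test needs at least two pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    warning("zero-variance differences: paired test is degenerate, p = 1",
            call. = FALSE)
    return(list(p_value = 1, statistic = NA_real_, method = method,
                mean_difference = mean(d), degenerate = TRUE))
  }
  res <- if (method == "t") {
    stats::t.test(pairs$reference, pairs$estimated, paired = TRUE)
  } else {
    stats::wilcox.test(pairs$reference, pairs$estimated, paired = TRUE,
                       exact = FALSE)
  }
  list(p_value = unname(res$p.value), statistic = unname(res$statistic),
       method = method, mean_difference = mean(d), degenerate = FALSE)
}

#' Full agreement report between reference and estimated presses
#'
#' Convenience wrapper: aligns presses by bottom time, then computes MAE,
#' 0.5 cm tolerance accuracy and the paired test.
#'
#' @param reference,estimated data frames with `bottom_time_s`, `depth_cm`.
#' @param tol_cm tolerance for the accuracy criterion; default 0.5 cm.
#' @param window_s alignment window; see [align_presses()].
#' @param method test method; see [paired_depth_test()].
#' @return List with `n_pairs`, `mae_cm`, `accuracy_pct`, `p_value`,
#'   `test`, `alignment`.
#' @export
evaluate_against_reference <- function(reference, estimated, tol_cm = 0.5,
                                       window_s = 0.3,
                                       method = c("t", "wilcoxon")) {
  al <- align_presses(reference, estimated, window_s)
  test <- paired_depth_test(al$pairs, method)
  list(n_pairs = length(al$pairs$reference),
       mae_cm = mean_absolute_error(al$pairs),
       accuracy_pct = tolerance_accuracy(al$pairs, tol_cm),
       p_value = test$p_value,
       test = test,
       alignment = al)
}
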