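#' Run the full device evaluation on a dataset
#'
#' One-call driver for the standard evaluation: extracts comparative pairs,
#' applies the patient inclusion rule, and computes the point-accuracy
#' report, the reliability summary, per-series glycemic summaries and the
#' lag profile.
#'
#' @param dataset a `cgm_dataset`.
#' @param window_min pairing staleness window (minutes).
#' @param shifts shifts for the lag profile (see [time_shift_mard()]).
#' @param ci MARD confidence-interval method, see [mard()].
#' @return object of class `cgm_evaluation`: list with `pairs`,
#'   `inclusion`, `accuracy` (`cgm_accuracy`), `reliability`
#'   (`cgm_reliability`), `lag` (`lag_profile`), `stratified` (by glucose
#'   range and by daily variability).
#' @export
evaluate_cgm <- function(dataset, window_min = 5, shifts = 0:30, ci = "normal") {
  stopifnot(inherits(dataset, "cgm_dataset"))
  pairs <- extract_pairs(dataset, window_min = window_min)
  structure(list(
    pairs = pairs,
    inclusion = apply_inclusion(dataset, pairs),
    accuracy = accuracy_report(pairs, ci = ci),
    reliability = reliability_summary(dataset),
    lag = time_shift_mard(dataset, shifts = shifts, window_min = window_min),
    stratified = list(glucose_range = mard_by_glucose_range(pairs),
                      variability = mard_by_variability(pairs, dataset))
  ), class = "cgm_evaluation")
}

#' @export
print.cgm_evaluation <- function(x, ...) {
  cat("== CGM device evaluation ==\n")
  print(x$pairs)
  cat(sprintf("  patients included: %d of %d\n", sum(x$inclusion$included),
              nrow(x$inclusion)))
  print(x$accuracy)
  print(x$reliability)
  print(x$lag)
  invisible(x)
}
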