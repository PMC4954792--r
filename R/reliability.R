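#' Detect real-time display gaps in a sensor session
#'
#' A gap is a maximal run of missing display minutes between initialization
#' and removal: wherever consecutive displayed minutes differ by more than
#' one minute, the minutes in between form one gap (duration = difference
#' minus 1). A leading run of missing minutes between initialization and the
#' first displayed value is also a gap. Early removal is not a gap -- it
#' ends monitoring (removal causes are tabulated separately from gap
#' causes).
#'
#' If the session carries gap-cause annotations, each detected gap is tagged
#' with the annotated cause whose start time falls inside it (codes 1-7;
#' 1-3 device-related).
#'
#' @param session a `sensor_session`.
#' @return data.frame of class `gap_records`: `sensor_id`, `start`, `end`
#'   (timestamps of the first and last missing minute), `duration_min`,
#'   `category` (see [classify_gap()]), `cause_code` (NA when unannotated).
#' @export
detect_gaps <- function(session) {
  stopifnot(inherits(session, "sensor_session"))
  samp <- sort(minute_index(session$samples$timestamp))
  init <- minute_index(session$init_time)
  starts <- ends <- numeric(0)
  if (length(samp)) {
    if (samp[1] > init) {
      starts <- init
      ends <- samp[1] - 1
    }
    d <- diff(samp)
    idx <- which(d > 1)
    starts <- c(starts, samp[idx] + 1)
    ends <- c(ends, samp[idx + 1] - 1)
  } else if (minute_index(session$removal_time) > init) {
    starts <- init
    ends <- minute_index(session$removal_time) - 1
  }
  dur <- ends - starts + 1
  cause <- rep(NA_integer_, length(starts))
  if (!is.null(session$gap_causes) && nrow(session$gap_causes) && length(starts)) {
    ann_m <- minute_index(session$gap_causes$start_time)
    for (i in seq_along(starts)) {
      hit <- which(ann_m >= starts[i] & ann_m <= ends[i])
      if (length(hit)) {
        codes <- session$gap_causes$cause_code[hit]
        # one gap may span several annotated episodes; keep the majority cause
        cause[i] <- as.integer(names(sort(table(codes), decreasing = TRUE))[1])
      }
    }
  }
  out <- data.frame(sensor_id = rep(session$sensor_id, length(starts)),
                    start = minutes_to_posix(starts),
                    end = minutes_to_posix(ends),
                    duration_min = dur,
                    category = if (length(dur)) classify_gap(dur) else character(0),
                    cause_code = cause,
                    stringsAsFactors = FALSE)
  class(out) <- c("gap_records", "data.frame")
  out
}

#' Classify a display gap by duration
#'
#' Four duration categories describe the clinical significance of missing
#' real-time trend data: `very_brief` (< 15 min), `brief` (15-30 min,
#' inclusive), `prolonged` (31-120 min) and `very_prolonged` (> 120 min).
#' The 30- and 120-min edges belong to the shorter category.
#'
#' @param duration_min numeric vector of gap durations (minutes, >= 1).
#' @return character vector of categories.
#' @export
classify_gap <- function(duration_min) {
  stopifnot(all(duration_min >= 1))
  ifelse(duration_min < 15, "very_brief",
         ifelse(duration_min <= 30, "brief",
                ifelse(duration_min <= 120, "prolonged", "very_prolonged")))
}

#' Reliability summary over a set of sensor sessions
#'
#' Per sensor: expected monitoring minutes (72 h), actual monitoring minutes
#' (initialization to removal), displayed minutes, the two display
#' percentages (of expected and of actual time), gap minutes, and number of
#' calibrations. Cohort level: medians with interquartile range of the
#' per-sensor quantities, gap counts by duration category, gap-minute shares
#' by cause over both denominators (total gap minutes and total monitoring
#' minutes), and the consensus display criterion (display during more than
#' 95 % of monitoring time and no device-related gap of 30 min or more).
#'
#' @param sessions a list of `sensor_session` objects (see
#'   [sensor_sessions()]) or a `cgm_dataset`.
#' @param expected_hours expected monitoring time per sensor (h).
#' @param display_denominator denominator for the consensus >95 % display
#'   criterion: `"actual"` monitoring time (default) or `"expected"` 72 h.
#' @return object of class `cgm_reliability`: list with `per_sensor`
#'   (data.frame), `gaps` (all gap records), `cohort` (list of summaries)
#'   and `consensus` (list `display_ok`, `gaps_ok`, `pass`).
#' @export
reliability_summary <- function(sessions, expected_hours = 72,
                                display_denominator = c("actual", "expected")) {
  display_denominator <- match.arg(display_denominator)
  if (inherits(sessions, "cgm_dataset")) sessions <- sensor_sessions(sessions)
  stopifnot(length(sessions) >= 1)

  gaps <- do.call(rbind, lapply(sessions, detect_gaps))
  rownames(gaps) <- NULL

  per <- do.call(rbind, lapply(sessions, function(s) {
    actual <- minute_index(s$removal_time) - minute_index(s$init_time)
    displayed <- nrow(s$samples)
    data.frame(sensor_id = s$sensor_id, patient_id = s$patient_id,
               expected_min = expected_hours * 60,
               actual_min = actual, displayed_min = displayed,
               gap_min = actual - displayed,
               pct_display_of_expected = displayed / (expected_hours * 60) * 100,
               pct_display_of_actual = if (actual > 0) displayed / actual * 100 else NA_real_,
               n_calibrations = nrow(s$calibrations),
               removal_cause = s$removal_cause,
               premature = actual < expected_hours * 60,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL

  cat_levels <- c("very_brief", "brief", "prolonged", "very_prolonged")
  gap_counts <- table(factor(gaps$category, levels = cat_levels))

  cause_min <- tapply(gaps$duration_min, factor(gaps$cause_code, levels = 1:7), sum)
  cause_min[is.na(cause_min)] <- 0
  total_gap_min <- sum(gaps$duration_min)
  total_mon_min <- sum(per$actual_min)

  dev_gaps <- gaps[!is.na(gaps$cause_code) & gaps$cause_code %in% 1:3, , drop = FALSE]
  display_pct <- if (display_denominator == "actual") per$pct_display_of_actual
                 else per$pct_display_of_expected
  consensus <- list(
    display_ok = all(display_pct > 95, na.rm = TRUE),
    gaps_ok = !nrow(dev_gaps) || all(dev_gaps$duration_min < 30)
  )
  consensus$pass <- consensus$display_ok && consensus$gaps_ok

  cohort <- list(
    n_sensors = nrow(per),
    n_patients = length(unique(per$patient_id)),
    actual_hours = median_iqr(per$actual_min / 60),
    displayed_hours = median_iqr(per$displayed_min / 60),
    pct_display_of_expected = median_iqr(per$pct_display_of_expected),
    pct_display_of_actual = median_iqr(per$pct_display_of_actual),
    gap_hours = median_iqr(per$gap_min / 60),
    n_calibrations = median_iqr(per$n_calibrations),
    n_gaps = nrow(gaps),
    gap_counts = stats::setNames(as.integer(gap_counts), cat_levels),
    gap_category_pct = stats::setNames(as.numeric(gap_counts) / max(1, nrow(gaps)) * 100,
                                       cat_levels),
    total_gap_min = total_gap_min,
    total_monitoring_min = total_mon_min,
    cause_share_of_gap_min =
      if (total_gap_min > 0) as.numeric(cause_min) / total_gap_min * 100 else rep(0, 7),
    cause_share_of_monitoring_min =
      if (total_mon_min > 0) as.numeric(cause_min) / total_mon_min * 100 else rep(0, 7),
    n_premature = sum(per$premature),
    pct_premature = mean(per$premature) * 100,
    removal_causes = table(factor(per$removal_cause[per$premature], levels = 1:7))
  )
  names(cohort$cause_share_of_gap_min) <- names(cohort$cause_share_of_monitoring_min) <- 1:7

  structure(list(per_sensor = per, gaps = gaps, cohort = cohort,
                 consensus = consensus,
                 display_denominator = display_denominator),
            class = "cgm_reliability")
}

#' @export
print.cgm_reliability <- function(x, ...) {
  co <- x$cohort
  cat("<cgm_reliability>", co$n_sensors, "sensors,", co$n_patients, "patients\n")
  cat(sprintf("  actual monitoring time   %s h\n", fmt_miqr(x$per_sensor$actual_min / 60)))
  cat(sprintf("  real-time data display   %s h\n", fmt_miqr(x$per_sensor$displayed_min / 60)))
  cat(sprintf("  display / expected 72 h  %s %%\n", fmt_miqr(x$per_sensor$pct_display_of_expected)))
  cat(sprintf("  display / actual time    %s %%\n", fmt_miqr(x$per_sensor$pct_display_of_actual)))
  cat(sprintf("  gaps: %d (%s)\n", co$n_gaps,
              paste(sprintf("%s %d", names(co$gap_counts), co$gap_counts), collapse = ", ")))
  cat(sprintf("  premature removals: %d of %d sensors (%.1f %%)\n",
              co$n_premature, co$n_sensors, co$pct_premature))
  cat(sprintf("  consensus display criterion (>95 %% of %s time, device gaps <30 min): %s\n",
              x$display_denominator, if (x$consensus$pass) "PASS" else "FAIL"))
  invisible(x)
}
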