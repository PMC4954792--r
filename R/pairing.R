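#' Classify a session's calibration events
#'
#' Calibration entries fall into three kinds. The first three events of a
#' session (the start-up entry and the entries after the first and second
#' running hour) are `initial`. An event preceded by a real-time display gap
#' longer than 15 minutes is `post_gap` (the device demands a fresh blood
#' glucose entry after such gaps). Everything else -- the routine 8-hourly
#' entries -- is `scheduled`. Reference values behind `initial` and
#' `post_gap` calibrations are excluded from the point-accuracy pairing;
#' `scheduled` ones are retained (flagged, so they can be filtered).
#'
#' @param session a `sensor_session`.
#' @return The session's calibration table with an added `kind` column
#'   (`initial`, `post_gap` or `scheduled`).
#' @export
classify_calibrations <- function(session) {
  stopifnot(inherits(session, "sensor_session"))
  cals <- session$calibrations
  cals <- cals[order(cals$timestamp), , drop = FALSE]
  rownames(cals) <- NULL
  n <- nrow(cals)
  if (n == 0) {
    cals$kind <- character(0)
    return(cals)
  }
  init_m <- minute_index(session$init_time)
  rem_m <- minute_index(session$removal_time)
  ev_m <- minute_index(cals$timestamp)
  if (any(ev_m < init_m | ev_m > rem_m)) {
    bad <- which(ev_m < init_m | ev_m > rem_m)[1]
    stop(sprintf("calibration at %s outside session span of sensor %s",
                 format(cals$timestamp[bad]), session$sensor_id), call. = FALSE)
  }
  samp_m <- minute_index(session$samples$timestamp)
  kind <- character(n)
  for (i in seq_len(n)) {
    if (i <= 3) {
      kind[i] <- "initial"
      next
    }
    # missing display minutes immediately before the event; the event minute
    # itself may carry a displayed value (display resumes with the entry)
    prev <- samp_m[samp_m < ev_m[i]]
    gap_before <- if (length(prev)) ev_m[i] - max(prev) - 1 else ev_m[i] - init_m
    kind[i] <- if (gap_before > 15) "post_gap" else "scheduled"
  }
  cals$kind <- kind
  cals
}

#' Classify a single calibration event
#'
#' @param session a `sensor_session`.
#' @param timestamp the event's timestamp (must match a calibration of the
#'   session).
#' @return One of `"initial"`, `"post_gap"`, `"scheduled"`.
#' @export
classify_calibration <- function(session, timestamp) {
  cals <- classify_calibrations(session)
  i <- match(minute_index(as_minute(timestamp)), minute_index(cals$timestamp))
  if (is.na(i)) {
    stop("no calibration event at ", format(as_minute(timestamp)),
         " in sensor ", session$sensor_id, call. = FALSE)
  }
  cals$kind[i]
}

#' Extract comparative reference/sensor pairs for point-accuracy analysis
#'
#' Each blood-gas reference value taken while a sensor session was running is
#' matched to the latest displayed sensor value at or before the reference
#' timestamp, within a staleness window (default 5 min). References that
#' served as initial or post-gap calibrations are excluded; references that
#' served as scheduled calibrations are paired but flagged. References taken
#' during display gaps wider than the window are counted as unpairable;
#' references outside any session span are ignored for accuracy (they remain
#' available to the glycemic-metric analyses).
#'
#' The absolute relative difference of each pair is
#' `ARD = |reference - sensor| / reference * 100`.
#'
#' @param dataset a `cgm_dataset`.
#' @param window_min staleness window in minutes: the sensor value must lie
#'   within this many minutes at or before the reference draw. A same-minute
#'   sensor value is used when present.
#' @param include_scheduled_calibrations keep pairs whose reference also
#'   served as a scheduled (8-hourly) calibration? Default `TRUE`; they are
#'   flagged in `is_calibration` either way.
#' @return A data.frame of class `cgm_pairs` with columns `patient_id`,
#'   `sensor_id`, `timestamp`, `reference_mgdl`, `sensor_mgdl`, `ard_pct`,
#'   `source`, `is_calibration`, `sensor_age_min`, and attribute `counts`
#'   (named vector: `total_references`, `paired`, `excluded_calibration`,
#'   `unpairable`, `out_of_session`).
#' @export
extract_pairs <- function(dataset, window_min = 5,
                          include_scheduled_calibrations = TRUE) {
  stopifnot(inherits(dataset, "cgm_dataset"), window_min >= 0)
  sessions <- sensor_sessions(dataset)
  ref <- dataset$reference
  n_ref <- nrow(ref)
  ref_m <- minute_index(ref$timestamp)

  # session lookup per patient
  ses_pat <- vapply(sessions, `[[`, "", "patient_id")
  ses_init <- vapply(sessions, function(s) minute_index(s$init_time), 0)
  ses_rem <- vapply(sessions, function(s) minute_index(s$removal_time), 0)

  cal_kind <- lapply(sessions, classify_calibrations)

  rows <- vector("list", n_ref)
  status <- character(n_ref)
  for (i in seq_len(n_ref)) {
    t <- ref_m[i]
    cand <- which(ses_pat == ref$patient_id[i] & ses_init <= t & ses_rem >= t)
    if (!length(cand)) {
      status[i] <- "out_of_session"
      next
    }
    s_idx <- cand[1]
    ses <- sessions[[s_idx]]
    ck <- cal_kind[[s_idx]]
    cal_i <- match(t, minute_index(ck$timestamp))
    is_cal <- !is.na(cal_i)
    if (is_cal && ck$kind[cal_i] %in% c("initial", "post_gap")) {
      status[i] <- "excluded_calibration"
      next
    }
    if (is_cal && !include_scheduled_calibrations) {
      status[i] <- "excluded_calibration"
      next
    }
    samp_m <- minute_index(ses$samples$timestamp)
    ok <- which(samp_m <= t & samp_m >= t - window_min)
    if (!length(ok)) {
      status[i] <- "unpairable"
      next
    }
    j <- ok[length(ok)]
    sensor_val <- ses$samples$glucose_mgdl[j]
    status[i] <- "paired"
    rows[[i]] <- data.frame(
      patient_id = ref$patient_id[i], sensor_id = ses$sensor_id,
      timestamp = ref$timestamp[i], reference_mgdl = ref$glucose_mgdl[i],
      sensor_mgdl = sensor_val,
      ard_pct = abs(ref$glucose_mgdl[i] - sensor_val) / ref$glucose_mgdl[i] * 100,
      source = ref$source[i], is_calibration = is_cal,
      sensor_age_min = t - samp_m[j],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(pairs)) {
    pairs <- data.frame(patient_id = character(0), sensor_id = character(0),
                        timestamp = minutes_to_posix(numeric(0)),
                        reference_mgdl = numeric(0), sensor_mgdl = numeric(0),
                        ard_pct = numeric(0), source = character(0),
                        is_calibration = logical(0), sensor_age_min = numeric(0))
  }
  rownames(pairs) <- NULL
  counts <- c(total_references = n_ref,
              paired = sum(status == "paired"),
              excluded_calibration = sum(status == "excluded_calibration"),
              unpairable = sum(status == "unpairable"),
              out_of_session = sum(status == "out_of_session"))
  attr(pairs, "counts") <- counts
  class(pairs) <- c("cgm_pairs", "data.frame")
  pairs
}

#' Apply the per-patient accuracy-analysis inclusion rule
#'
#' A patient enters the point-accuracy analysis when monitored for at least
#' `min_hours` (default 48 h) or contributing at least `min_pairs`
#' comparative readings (default 12).
#'
#' @param dataset a `cgm_dataset`.
#' @param pairs a `cgm_pairs` data.frame from [extract_pairs()].
#' @param min_hours,min_pairs the two alternative inclusion thresholds.
#' @return data.frame with one row per patient: `patient_id`,
#'   `monitored_hours`, `n_pairs`, `included`, `reason`.
#' @export
apply_inclusion <- function(dataset, pairs, min_hours = 48, min_pairs = 12) {
  stopifnot(inherits(dataset, "cgm_dataset"))
  ses <- dataset$sessions
  hrs <- tapply((minute_index(ses$removal_time) - minute_index(ses$init_time)) / 60,
                ses$patient_id, sum)
  ids <- names(hrs)
  npairs <- vapply(ids, function(p) sum(pairs$patient_id == p), 0L)
  included <- unname(hrs >= min_hours | npairs >= min_pairs)
  reason <- ifelse(hrs >= min_hours, sprintf(">=%g h monitored", min_hours),
            ifelse(npairs >= min_pairs, sprintf(">=%g comparative readings", min_pairs),
                   "neither criterion met"))
  out <- data.frame(patient_id = ids, monitored_hours = unname(hrs),
                    n_pairs = unname(npairs), included = included,
                    reason = unname(reason), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.cgm_pairs <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("<cgm_pairs> %d comparative readings (%d patients)\n",
              nrow(x), length(unique(x$patient_id))))
  if (!is.null(counts)) {
    cat(sprintf("  of %d references: %d paired, %d calibration-excluded, %d unpairable, %d outside sessions\n",
                counts["total_references"], counts["paired"],
                counts["excluded_calibration"], counts["unpairable"],
                counts["out_of_session"]))
  }
  if (nrow(x)) cat(sprintf("  MARD %.1f %%\n", mean(x$ard_pct)))
  invisible(x)
}
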