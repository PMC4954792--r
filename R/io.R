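#' Assemble a CGM evaluation dataset
#'
#' Bundles the four core tables of a CGM device evaluation -- the per-minute
#' sensor trace, the intermittent blood-gas reference log, the calibration
#' log and the per-sensor session records -- plus optional covariate and
#' gap-cause annotations, into a validated `cgm_dataset` object consumed by
#' every downstream stage.
#'
#' All timestamps are floored to 1-minute resolution (the device emits one
#' value per minute); sub-minute input triggers a warning. Glucose is in
#' mg/dl throughout.
#'
#' @param cgm data.frame with columns `patient_id`, `sensor_id`, `timestamp`,
#'   `glucose_mgdl`: the displayed real-time sensor values, one row per
#'   displayed minute. Missing minutes are represented by absence of a row.
#' @param reference data.frame with columns `patient_id`, `timestamp`,
#'   `glucose_mgdl`, `source` (`"arterial"` or `"venous"`): blood-gas
#'   analyzer measurements.
#' @param calibrations data.frame with columns `patient_id`, `sensor_id`,
#'   `timestamp`, `reference_mgdl`: blood glucose entries used to calibrate
#'   the sensor.
#' @param sessions data.frame with columns `patient_id`, `sensor_id`,
#'   `init_time`, `removal_time`, `removal_cause` (integer code 1-7; codes
#'   1-3 are device-related).
#' @param covariates optional data.frame with columns `patient_id`,
#'   `timestamp`, `name`, `value` (long format; e.g. `pO2`, `temperature`,
#'   `hemoglobin`, `potassium`, `lactate`, `pH`, `SOFA`, `SIRS`, `diabetes`,
#'   `vasopressor`). Analyses that need absent covariates skip them.
#' @param gap_causes optional data.frame with columns `patient_id`,
#'   `sensor_id`, `start_time`, `cause_code` (1-7; 1-3 device-related)
#'   annotating the cause of the display gap starting at `start_time`.
#' @return An object of class `cgm_dataset`.
#' @seealso [read_cgm_dataset()], [sensor_sessions()], [extract_pairs()]
#' @export
cgm_dataset <- function(cgm, reference, calibrations, sessions,
                        covariates = NULL, gap_causes = NULL) {
  cgm <- .prep_table(cgm, c("patient_id", "sensor_id", "timestamp", "glucose_mgdl"),
                     value_col = "glucose_mgdl", table = "cgm")
  reference <- .prep_table(reference, c("patient_id", "timestamp", "glucose_mgdl", "source"),
                           value_col = "glucose_mgdl", table = "reference")
  calibrations <- .prep_table(calibrations,
                              c("patient_id", "sensor_id", "timestamp", "reference_mgdl"),
                              value_col = "reference_mgdl", table = "calibrations")
  sessions <- .prep_sessions(sessions)

  bad_src <- setdiff(unique(reference$source), c("arterial", "venous"))
  if (length(bad_src)) {
    stop("unknown reference source tag(s): ", paste(bad_src, collapse = ", "),
         " (expected 'arterial' or 'venous')", call. = FALSE)
  }

  key <- paste(cgm$sensor_id, format(cgm$timestamp))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop(sprintf("duplicate (sensor_id, timestamp) in cgm table at row %d: %s @ %s",
                 dup, cgm$sensor_id[dup], format(cgm$timestamp[dup])), call. = FALSE)
  }
  ord <- order(cgm$sensor_id, cgm$timestamp)
  cgm <- cgm[ord, , drop = FALSE]
  reference <- reference[order(reference$patient_id, reference$timestamp), , drop = FALSE]
  calibrations <- calibrations[order(calibrations$sensor_id, calibrations$timestamp), , drop = FALSE]
  rownames(cgm) <- rownames(reference) <- rownames(calibrations) <- NULL

  if (!is.null(covariates)) {
    stopifnot(all(c("patient_id", "timestamp", "name", "value") %in% names(covariates)))
    covariates$timestamp <- as_minute(covariates$timestamp)
    covariates$value <- as.numeric(covariates$value)
  }
  if (!is.null(gap_causes)) {
    stopifnot(all(c("patient_id", "sensor_id", "start_time", "cause_code") %in% names(gap_causes)))
    gap_causes$start_time <- as_minute(gap_causes$start_time)
    gap_causes$cause_code <- as.integer(gap_causes$cause_code)
  }

  structure(list(cgm = cgm, reference = reference, calibrations = calibrations,
                 sessions = sessions, covariates = covariates,
                 gap_causes = gap_causes),
            class = "cgm_dataset")
}

#' @noRd
.prep_table <- function(df, cols, value_col, table) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s table lacks column(s): %s", table,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- as.data.frame(df)[cols]
  ts <- as_minute(df$timestamp)
  if (anyNA(ts) && !anyNA(df$timestamp)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("%s table: malformed timestamp at row %d: '%s'", table, bad,
                 as.character(df$timestamp[bad])), call. = FALSE)
  }
  df$timestamp <- ts
  v <- as.numeric(df[[value_col]])
  if (any(!is.finite(v) | v <= 0)) {
    bad <- which(!is.finite(v) | v <= 0)[1]
    stop(sprintf("%s table: non-positive or non-finite glucose at row %d", table, bad),
         call. = FALSE)
  }
  df[[value_col]] <- v
  df$patient_id <- as.character(df$patient_id)
  if ("sensor_id" %in% cols) df$sensor_id <- as.character(df$sensor_id)
  if ("source" %in% cols) df$source <- as.character(df$source)
  df
}

#' @noRd
.prep_sessions <- function(sessions) {
  cols <- c("patient_id", "sensor_id", "init_time", "removal_time", "removal_cause")
  missing_cols <- setdiff(cols, names(sessions))
  if (length(missing_cols)) {
    stop("sessions table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sessions <- as.data.frame(sessions)[cols]
  sessions$patient_id <- as.character(sessions$patient_id)
  sessions$sensor_id <- as.character(sessions$sensor_id)
  sessions$init_time <- as_minute(sessions$init_time)
  sessions$removal_time <- as_minute(sessions$removal_time)
  sessions$removal_cause <- as.integer(sessions$removal_cause)
  if (anyDuplicated(sessions$sensor_id)) {
    stop("duplicate sensor_id in sessions table", call. = FALSE)
  }
  sessions[order(sessions$patient_id, sessions$init_time), , drop = FALSE]
}

#' Read a CGM evaluation dataset from CSV files
#'
#' Reads the comma-separated dialect (header row, UTF-8, ISO-8601 timestamps):
#' `cgm.csv` (`patient_id,sensor_id,timestamp,glucose_mgdl`), `reference.csv`
#' (`patient_id,timestamp,glucose_mgdl,source`), `calibrations.csv`
#' (`patient_id,sensor_id,timestamp,reference_mgdl`), `sessions.csv`
#' (`patient_id,sensor_id,init_time,removal_time,removal_cause`), and
#' optionally `covariates.csv` (`patient_id,timestamp,name,value`) and
#' `gap_causes.csv` (`patient_id,sensor_id,start_time,cause_code`).
#'
#' @param cgm_path,reference_path,calibration_path,sessions_path paths to the
#'   four required CSV files.
#' @param covariate_path,gap_cause_path optional paths.
#' @return A [cgm_dataset()] object.
#' @export
read_cgm_dataset <- function(cgm_path, reference_path, calibration_path,
                             sessions_path, covariate_path = NULL,
                             gap_cause_path = NULL) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = NA, check.names = TRUE)
  cgm_dataset(
    cgm = rd(cgm_path),
    reference = rd(reference_path),
    calibrations = rd(calibration_path),
    sessions = rd(sessions_path),
    covariates = if (!is.null(covariate_path)) rd(covariate_path),
    gap_causes = if (!is.null(gap_cause_path)) rd(gap_cause_path)
  )
}

#' Write a CGM evaluation dataset as CSV files
#'
#' Writes the same dialect [read_cgm_dataset()] reads, so that
#' `read_cgm_dataset()` on the written files reproduces the dataset exactly.
#'
#' @param dataset a `cgm_dataset`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cgm_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cgm_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    for (col in intersect(c("timestamp", "init_time", "removal_time", "start_time"), names(df)))
      df[[col]] <- format(df[[col]], "%Y-%m-%dT%H:%M:%S", tz = .tz)
    df
  }
  paths <- c(cgm = file.path(dir, "cgm.csv"),
             reference = file.path(dir, "reference.csv"),
             calibrations = file.path(dir, "calibrations.csv"),
             sessions = file.path(dir, "sessions.csv"))
  utils::write.csv(fmt(dataset$cgm), paths["cgm"], row.names = FALSE)
  utils::write.csv(fmt(dataset$reference), paths["reference"], row.names = FALSE)
  utils::write.csv(fmt(dataset$calibrations), paths["calibrations"], row.names = FALSE)
  utils::write.csv(fmt(dataset$sessions), paths["sessions"], row.names = FALSE)
  if (!is.null(dataset$covariates)) {
    paths["covariates"] <- file.path(dir, "covariates.csv")
    utils::write.csv(fmt(dataset$covariates), paths["covariates"], row.names = FALSE)
  }
  if (!is.null(dataset$gap_causes)) {
    paths["gap_causes"] <- file.path(dir, "gap_causes.csv")
    utils::write.csv(fmt(dataset$gap_causes), paths["gap_causes"], row.names = FALSE)
  }
  invisible(paths)
}

#' Split a dataset into per-sensor session objects
#'
#' @param dataset a `cgm_dataset`.
#' @return A named list of `sensor_session` objects (one per row of the
#'   sessions table), each holding the session's displayed samples,
#'   calibration events, init/removal times and removal cause.
#' @export
sensor_sessions <- function(dataset) {
  stopifnot(inherits(dataset, "cgm_dataset"))
  out <- lapply(seq_len(nrow(dataset$sessions)), function(i) {
    s <- dataset$sessions[i, ]
    samples <- dataset$cgm[dataset$cgm$sensor_id == s$sensor_id, , drop = FALSE]
    cals <- dataset$calibrations[dataset$calibrations$sensor_id == s$sensor_id, , drop = FALSE]
    gc <- NULL
    if (!is.null(dataset$gap_causes)) {
      gc <- dataset$gap_causes[dataset$gap_causes$sensor_id == s$sensor_id, , drop = FALSE]
    }
    structure(list(sensor_id = s$sensor_id, patient_id = s$patient_id,
                   init_time = s$init_time, removal_time = s$removal_time,
                   removal_cause = s$removal_cause,
                   samples = samples, calibrations = cals, gap_causes = gc),
              class = "sensor_session")
  })
  names(out) <- dataset$sessions$sensor_id
  out
}

#' Validate a sensor session against its structural invariants
#'
#' Checks that displayed samples are strictly increasing in time, lie between
#' initialization and removal, that the monitored span does not exceed the
#' 72-h sensor lifetime (plus a 60-min scheduling tolerance), and that all
#' glucose values are positive and finite.
#'
#' @param session a `sensor_session` (see [sensor_sessions()]).
#' @return Character vector of violations; empty if and only if the session
#'   is well formed.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "sensor_session"))
  v <- character(0)
  ts <- minute_index(session$samples$timestamp)
  if (length(ts) && any(diff(ts) <= 0)) {
    v <- c(v, "samples not strictly increasing in time")
  }
  if (length(ts)) {
    if (min(ts) < minute_index(session$init_time)) {
      v <- c(v, "sample before init_time")
    }
    if (max(ts) > minute_index(session$removal_time)) {
      v <- c(v, "sample after removal_time")
    }
  }
  span_min <- minute_index(session$removal_time) - minute_index(session$init_time)
  if (span_min < 0) v <- c(v, "removal_time before init_time")
  if (span_min > 72 * 60 + 60) {
    v <- c(v, sprintf("monitoring span %.1f h exceeds 72 h sensor lifetime", span_min / 60))
  }
  if (length(session$samples$glucose_mgdl) &&
      any(!is.finite(session$samples$glucose_mgdl) | session$samples$glucose_mgdl <= 0)) {
    v <- c(v, "non-positive or non-finite sensor glucose value")
  }
  if (!is.na(session$removal_cause) &&
      !(session$removal_cause %in% 1:7)) {
    v <- c(v, "removal_cause outside 1-7")
  }
  v
}

#' @export
print.cgm_dataset <- function(x, ...) {
  cat("<cgm_dataset>\n")
  cat(sprintf("  patients:      %d\n", length(unique(x$sessions$patient_id))))
  cat(sprintf("  sensors:       %d\n", nrow(x$sessions)))
  cat(sprintf("  sensor values: %d\n", nrow(x$cgm)))
  cat(sprintf("  references:    %d (%s)\n", nrow(x$reference),
              paste(sprintf("%s %d", names(table(x$reference$source)),
                            as.integer(table(x$reference$source))), collapse = ", ")))
  cat(sprintf("  calibrations:  %d\n", nrow(x$calibrations)))
  if (!is.null(x$covariates))
    cat(sprintf("  covariates:    %s\n", paste(unique(x$covariates$name), collapse = ", ")))
  invisible(x)
}
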