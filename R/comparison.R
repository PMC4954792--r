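# Intra-individual comparisons of glycemic control: 72-h windows before /
# during / after monitoring (longitudinal), and intermittent reference vs
# the full continuous series over the same span (parallel).

#' @noRd
.metric_names <- c("n_readings", "events_hypo", "events_hyper",
                   "time_in_target_pct", "time_below_target_pct",
                   "time_above_target_pct", "min", "max", "mean", "sd", "gli")

#' @noRd
.metric_row <- function(gs) {
  vapply(.metric_names, function(m) as.numeric(gs[[m]] %||% NA_real_), 0)
}

#' Longitudinal comparison of glycemic control before/during/after CGM
#'
#' For each patient with enough reference data on both sides of the
#' monitored period, computes glycemic summaries from the intermittent
#' reference series in three contiguous windows: the `window_hours`
#' (default 72 h) before the first sensor start, the actual monitored span
#' (first sensor start to last removal), and the `window_hours` after the
#' last removal. Patients whose reference readings do not cover at least
#' `min_coverage` of the before and after windows are excluded and listed.
#' Cohort medians/IQR are computed per metric across patients; a Friedman
#' test across the three windows and pairwise paired Wilcoxon tests are
#' reported per metric.
#'
#' @param dataset a `cgm_dataset`.
#' @param window_hours width of the before/after windows (h).
#' @param min_coverage minimum fraction of a window that the patient's
#'   reference readings must span for the window to count as complete.
#' @param target target range passed to [glycemic_summary()].
#' @return object of class `cgm_longitudinal`: `per_patient` (long
#'   data.frame of metrics), `cohort` (metric x window medians/IQR),
#'   `tests` (per-metric Friedman and pairwise Wilcoxon p-values),
#'   `excluded` (patient ids).
#' @export
longitudinal_compare <- function(dataset, window_hours = 72,
                                 min_coverage = 0.8, target = c(71, 149)) {
  stopifnot(inherits(dataset, "cgm_dataset"))
  ses <- dataset$sessions
  ref <- dataset$reference
  ref_m <- minute_index(ref$timestamp)
  w_min <- window_hours * 60

  per <- list(); excluded <- character(0)
  for (p in unique(ses$patient_id)) {
    sp <- ses[ses$patient_id == p, ]
    cgm_start <- min(minute_index(sp$init_time))
    cgm_end <- max(minute_index(sp$removal_time))
    windows <- list(
      before = c(cgm_start - w_min, cgm_start - 1),
      during = c(cgm_start, cgm_end),
      after = c(cgm_end + 1, cgm_end + w_min)
    )
    rows <- lapply(names(windows), function(w) {
      lim <- windows[[w]]
      sel <- ref$patient_id == p & ref_m >= lim[1] & ref_m <= lim[2]
      if (sum(sel) < 2) return(NULL)
      span <- diff(range(ref_m[sel]))
      need <- if (w == "during") 0 else min_coverage * w_min
      if (span < need) return(NULL)
      gs <- glycemic_summary(ref$timestamp[sel], ref$glucose_mgdl[sel], target)
      cbind(data.frame(patient_id = p, window = w, stringsAsFactors = FALSE),
            as.data.frame(as.list(.metric_row(gs))))
    })
    if (any(vapply(rows, is.null, TRUE))) {
      excluded <- c(excluded, p)
      next
    }
    per[[p]] <- do.call(rbind, rows)
  }
  if (!length(per)) {
    stop("no patient has complete before/during/after reference coverage",
         call. = FALSE)
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  per$window <- factor(per$window, levels = c("before", "during", "after"))

  cohort <- lapply(.metric_names, function(m) {
    sapply(levels(per$window), function(w) median_iqr(per[[m]][per$window == w]))
  })
  names(cohort) <- .metric_names

  tests <- lapply(.metric_names, function(m) {
    mat <- stats::reshape(per[c("patient_id", "window", m)],
                          direction = "wide", idvar = "patient_id",
                          timevar = "window")
    y <- as.matrix(mat[, -1])
    out <- list(friedman_p = NA_real_, pairwise_p = c(before_during = NA_real_,
                before_after = NA_real_, during_after = NA_real_))
    if (nrow(y) >= 2) {
      ft <- tryCatch(stats::friedman.test(y), error = function(e) NULL)
      if (!is.null(ft)) out$friedman_p <- ft$p.value
      pw <- function(i, j) {
        if (all(y[, i] == y[, j])) return(1)
        suppressWarnings(stats::wilcox.test(y[, i], y[, j], paired = TRUE,
                                            exact = FALSE)$p.value)
      }
      out$pairwise_p <- c(before_during = pw(1, 2), before_after = pw(1, 3),
                          during_after = pw(2, 3))
    }
    out
  })
  names(tests) <- .metric_names

  structure(list(per_patient = per, cohort = cohort, tests = tests,
                 excluded = excluded, window_hours = window_hours),
            class = "cgm_longitudinal")
}

#' Parallel comparison of intermittent versus continuous monitoring
#'
#' Restricts to patients whose per-patient MARD is below `mard_threshold`
#' (default 14 %, the consensus accuracy bound -- the comparison is only
#' meaningful where the device read accurately), then computes glycemic
#' summaries over the monitored span from (a) the intermittent reference
#' series, including readings taken during display gaps, and (b) the full
#' continuous sensor series, and compares each metric across patients with
#' paired Wilcoxon tests.
#'
#' @param dataset a `cgm_dataset`.
#' @param pairs a `cgm_pairs` data.frame (for per-patient MARD).
#' @param mard_threshold accuracy filter (%); `Inf` keeps every patient.
#' @param target target range passed to [glycemic_summary()].
#' @return object of class `cgm_parallel`: `per_patient` (long data.frame,
#'   series `intermittent` / `cgm`), `cohort`, `tests` (per-metric paired
#'   Wilcoxon p), `patients` (ids retained). Empty report (0 patients) when
#'   none qualifies.
#' @export
parallel_compare <- function(dataset, pairs, mard_threshold = 14,
                             target = c(71, 149)) {
  stopifnot(inherits(dataset, "cgm_dataset"), is.data.frame(pairs))
  pat_mard <- tapply(pairs$ard_pct, pairs$patient_id, mean)
  keep <- names(pat_mard)[pat_mard < mard_threshold]
  ses <- dataset$sessions
  ref <- dataset$reference
  ref_m <- minute_index(ref$timestamp)
  cgm_m <- minute_index(dataset$cgm$timestamp)

  per <- list()
  for (p in keep) {
    sp <- ses[ses$patient_id == p, ]
    span <- c(min(minute_index(sp$init_time)), max(minute_index(sp$removal_time)))
    sel_ref <- ref$patient_id == p & ref_m >= span[1] & ref_m <= span[2]
    sel_cgm <- dataset$cgm$patient_id == p & cgm_m >= span[1] & cgm_m <= span[2]
    if (sum(sel_ref) < 2 || sum(sel_cgm) < 2) next
    gs_i <- glycemic_summary(ref$timestamp[sel_ref], ref$glucose_mgdl[sel_ref], target)
    gs_c <- glycemic_summary(dataset$cgm$timestamp[sel_cgm],
                             dataset$cgm$glucose_mgdl[sel_cgm], target)
    per[[p]] <- rbind(
      cbind(data.frame(patient_id = p, series = "intermittent",
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(.metric_row(gs_i)))),
      cbind(data.frame(patient_id = p, series = "cgm", stringsAsFactors = FALSE),
            as.data.frame(as.list(.metric_row(gs_c)))))
  }
  if (!length(per)) {
    return(structure(list(per_patient = NULL, cohort = NULL, tests = NULL,
                          patients = character(0),
                          mard_threshold = mard_threshold),
                     class = "cgm_parallel"))
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL

  cohort <- lapply(.metric_names, function(m) {
    sapply(c("intermittent", "cgm"), function(s) median_iqr(per[[m]][per$series == s]))
  })
  names(cohort) <- .metric_names

  tests <- vapply(.metric_names, function(m) {
    a <- per[[m]][per$series == "intermittent"]
    b <- per[[m]][per$series == "cgm"]
    if (length(a) < 2 || all(a == b)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
  }, 0)

  structure(list(per_patient = per, cohort = cohort, tests = tests,
                 patients = unique(per$patient_id),
                 mard_threshold = mard_threshold),
            class = "cgm_parallel")
}

#' @export
print.cgm_longitudinal <- function(x, ...) {
  cat("<cgm_longitudinal>", length(unique(x$per_patient$patient_id)),
      "patients with complete windows\n")
  if (length(x$excluded)) {
    cat("  excluded (incomplete windows):", paste(x$excluded, collapse = ", "), "\n")
  }
  for (m in .metric_names) {
    co <- x$cohort[[m]]
    cat(sprintf("  %-22s before %s  during %s  after %s  (Friedman p %s)\n", m,
                sprintf("%.1f", co["median", "before"]),
                sprintf("%.1f", co["median", "during"]),
                sprintf("%.1f", co["median", "after"]),
                format.pval(x$tests[[m]]$friedman_p, digits = 2)))
  }
  invisible(x)
}

#' @export
print.cgm_parallel <- function(x, ...) {
  n <- length(unique(x$per_patient$patient_id))
  cat(sprintf("<cgm_parallel> %d patients with MARD < %g %%\n",
              if (is.null(x$per_patient)) 0 else n, x$mard_threshold))
  if (is.null(x$per_patient)) return(invisible(x))
  for (m in .metric_names) {
    co <- x$cohort[[m]]
    cat(sprintf("  %-22s intermittent %s  cgm %s  (Wilcoxon p %s)\n", m,
                sprintf("%.1f", co["median", "intermittent"]),
                sprintf("%.1f", co["median", "cgm"]),
                format.pval(x$tests[[m]], digits = 2)))
  }
  invisible(x)
}
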