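#' Accuracy stratified by blood glucose range
#'
#' Splits comparative pairs into reference-glucose strata (default the
#' hypoglycemic <80, mid 80-179, and severely hyperglycemic >179 mg/dl
#' ranges), reports the per-stratum ARD median with IQR, and tests for a
#' difference across strata with the Kruskal-Wallis test.
#'
#' @param pairs a `cgm_pairs` data.frame.
#' @param breaks interior stratum edges (mg/dl); the default `c(80, 180)`
#'   produces `<80`, `80-179`, `>=180`.
#' @return object of class `stratified_mard`: list with `strata`
#'   (data.frame: label, n, median, q1, q3), `test` (Kruskal-Wallis
#'   statistic, df, p; `NA` when fewer than two non-empty strata) and
#'   `by` = "glucose_range".
#' @export
mard_by_glucose_range <- function(pairs, breaks = c(80, 180)) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1)
  edges <- c(0, breaks, Inf)
  labels <- character(length(breaks) + 1)
  labels[1] <- sprintf("<%g", breaks[1])
  if (length(breaks) > 1) {
    for (i in seq_len(length(breaks) - 1)) {
      labels[i + 1] <- sprintf("%g-%g", breaks[i], breaks[i + 1] - 1)
    }
  }
  labels[length(labels)] <- sprintf(">=%g", breaks[length(breaks)])
  stratum <- cut(pairs$reference_mgdl, breaks = edges, labels = labels,
                 right = FALSE)
  .stratified_mard(pairs$ard_pct, stratum, by = "glucose_range")
}

#' @noRd
.stratified_mard <- function(ard, stratum, by, unassigned = 0L) {
  strata <- do.call(rbind, lapply(levels(stratum), function(l) {
    a <- ard[stratum == l & !is.na(stratum)]
    m <- median_iqr(a)
    data.frame(stratum = l, n = length(a), mard_median = m["median"],
               q1 = m["q1"], q3 = m["q3"], stringsAsFactors = FALSE)
  }))
  rownames(strata) <- NULL
  keep <- !is.na(stratum)
  nonempty <- strata$stratum[strata$n > 0]
  test <- list(statistic = NA_real_, df = NA_real_, p = NA_real_, method = NA_character_)
  if (length(nonempty) >= 2) {
    if (length(nonempty) == 2) {
      wt <- stats::wilcox.test(ard[keep] ~ droplevels(stratum[keep]), exact = FALSE)
      test <- list(statistic = unname(wt$statistic), df = NA_real_,
                   p = wt$p.value, method = "wilcoxon_rank_sum")
    } else {
      kt <- stats::kruskal.test(ard[keep], droplevels(stratum[keep]))
      test <- list(statistic = unname(kt$statistic),
                   df = unname(kt$parameter), p = kt$p.value,
                   method = "kruskal_wallis")
    }
  }
  structure(list(strata = strata, test = test, by = by,
                 n_unassigned = unassigned),
            class = "stratified_mard")
}

#' Accuracy stratified by daily blood glucose variability
#'
#' Assigns each pair to a variability stratum based on how far its reference
#' value sits from that patient's daily reference mean: within one daily
#' standard deviation (`within_1sd`) or beyond it (`beyond_1sd`). "Daily"
#' windows are 24-h blocks anchored at the patient's first monitoring
#' minute; the daily mean and SD are computed from the reference readings of
#' the block. Days with fewer than two reference readings leave their pairs
#' unassigned (reported, excluded from the test).
#'
#' @param pairs a `cgm_pairs` data.frame.
#' @param dataset the `cgm_dataset` the pairs came from (for the reference
#'   series and session start times).
#' @return object of class `stratified_mard` (two strata, rank-sum test).
#' @export
mard_by_variability <- function(pairs, dataset) {
  stopifnot(is.data.frame(pairs), inherits(dataset, "cgm_dataset"))
  ses <- dataset$sessions
  start_by_pat <- tapply(minute_index(ses$init_time), ses$patient_id, min)
  ref <- dataset$reference
  ref_m <- minute_index(ref$timestamp)
  pair_m <- minute_index(pairs$timestamp)
  stratum <- rep(NA_character_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$patient_id[i]
    anchor <- start_by_pat[[p]]
    day <- floor((pair_m[i] - anchor) / 1440)
    in_day <- ref$patient_id == p &
      ref_m >= anchor + day * 1440 & ref_m < anchor + (day + 1) * 1440
    vals <- ref$glucose_mgdl[in_day]
    if (length(vals) < 2) next
    mu <- mean(vals); s <- stats::sd(vals)
    if (s == 0) {
      stratum[i] <- "within_1sd"
    } else {
      stratum[i] <- if (abs(pairs$reference_mgdl[i] - mu) <= s) "within_1sd" else "beyond_1sd"
    }
  }
  f <- factor(stratum, levels = c("within_1sd", "beyond_1sd"))
  .stratified_mard(pairs$ard_pct, f, by = "daily_variability",
                   unassigned = sum(is.na(stratum)))
}

#' @export
print.stratified_mard <- function(x, ...) {
  cat(sprintf("<stratified_mard> by %s\n", x$by))
  for (i in seq_len(nrow(x$strata))) {
    s <- x$strata[i, ]
    cat(sprintf("  %-12s n=%4d  MARD median %.1f %% [%.1f/%.1f]\n",
                s$stratum, s$n, s$mard_median, s$q1, s$q3))
  }
  if (!is.na(x$test$p)) {
    cat(sprintf("  %s across strata: p = %s\n", x$test$method,
                format.pval(x$test$p, digits = 3)))
  }
  if (x$n_unassigned > 0) cat(sprintf("  unassigned pairs: %d\n", x$n_unassigned))
  invisible(x)
}

#' Covariate associations with per-pair accuracy
#'
#' For each continuous covariate (e.g. pO2, temperature, hemoglobin,
#' potassium, lactate, pH, SOFA), matches the nearest covariate value within
#' a tolerance (default 4 h) to each pair's timestamp and reports the
#' Spearman correlation between covariate and ARD. Binary covariates
#' (values only 0/1; e.g. SIRS, diabetes, vasopressor flags) are compared by
#' rank-sum test of ARD between the groups. Covariates absent from the
#' dataset are skipped with a notice; p-values are reported raw (no
#' multiplicity correction).
#'
#' @param pairs a `cgm_pairs` data.frame.
#' @param dataset a `cgm_dataset` carrying a covariate table.
#' @param tolerance_hours matching tolerance.
#' @return data.frame: `covariate`, `type` (`correlation`/`group`), `n`,
#'   `rho` (NA for group tests), `r_squared`, `p`.
#' @export
covariate_correlations <- function(pairs, dataset, tolerance_hours = 4) {
  stopifnot(is.data.frame(pairs), inherits(dataset, "cgm_dataset"))
  cov <- dataset$covariates
  if (is.null(cov) || !nrow(cov)) {
    message("no covariates in dataset; nothing to correlate")
    return(data.frame(covariate = character(0), type = character(0),
                      n = integer(0), rho = numeric(0), r_squared = numeric(0),
                      p = numeric(0)))
  }
  tol_min <- tolerance_hours * 60
  pair_m <- minute_index(pairs$timestamp)
  rows <- lapply(unique(cov$name), function(nm) {
    cn <- cov[cov$name == nm, ]
    matched <- rep(NA_real_, nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      cand <- cn[cn$patient_id == pairs$patient_id[i], ]
      if (!nrow(cand)) next
      d <- abs(minute_index(cand$timestamp) - pair_m[i])
      j <- which.min(d)
      if (d[j] <= tol_min) matched[i] <- cand$value[j]
    }
    ok <- !is.na(matched)
    n <- sum(ok)
    if (n < 3) return(NULL)
    vals <- matched[ok]
    ard <- pairs$ard_pct[ok]
    if (all(vals %in% c(0, 1))) {
      if (length(unique(vals)) < 2) return(NULL)
      wt <- stats::wilcox.test(ard ~ factor(vals), exact = FALSE)
      data.frame(covariate = nm, type = "group", n = n, rho = NA_real_,
                 r_squared = NA_real_, p = wt$p.value, stringsAsFactors = FALSE)
    } else {
      if (stats::sd(vals) == 0) return(NULL)
      ct <- suppressWarnings(stats::cor.test(ard, vals, method = "spearman",
                                             exact = FALSE))
      data.frame(covariate = nm, type = "correlation", n = n,
                 rho = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p = ct$p.value, stringsAsFactors = FALSE)
    }
  })
  skipped <- vapply(rows, is.null, TRUE)
  if (any(skipped)) {
    message("skipped covariate(s) with insufficient matchable data: ",
            paste(unique(cov$name)[skipped], collapse = ", "))
  }
  out <- do.call(rbind, rows[!skipped])
  if (is.null(out)) {
    out <- data.frame(covariate = character(0), type = character(0),
                      n = integer(0), rho = numeric(0), r_squared = numeric(0),
                      p = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Time-shifted MARD lag profile
#'
#' Recomputes MARD after shifting the pairing target by a fixed lag: at
#' shift `k` (minutes), each reference drawn at time `t` is paired with the
#' latest displayed sensor value at or before `t + k` (within the usual
#' staleness window). Positive shifts pair the reference with *later* sensor
#' values, probing whether the interstitial sensor lags blood; negative
#' shifts probe the opposite direction. The shift minimizing MARD estimates
#' the effective sensor delay. Shift 0 reproduces the unshifted MARD
#' exactly. Shifts at which no reference can be paired are omitted.
#'
#' The set of references used is fixed at the shift-0 pairing (so the
#' profile compares like with like); at each shift, references whose shifted
#' target leaves the session span or falls in a display gap are dropped from
#' that shift only.
#'
#' @param dataset a `cgm_dataset`.
#' @param shifts integer vector of shifts in minutes (default `0:30`).
#' @param window_min staleness window passed to the pairing rule.
#' @return object of class `lag_profile`: data.frame `profile` (`shift`,
#'   `mard`, `n`), `argmin_shift`, and the shift-0 MARD.
#' @export
time_shift_mard <- function(dataset, shifts = 0:30, window_min = 5) {
  stopifnot(inherits(dataset, "cgm_dataset"))
  base <- extract_pairs(dataset, window_min = window_min)
  if (!nrow(base)) stop("no pairable references at shift 0", call. = FALSE)
  sessions <- sensor_sessions(dataset)
  samp_by_sensor <- lapply(sessions, function(s) minute_index(s$samples$timestamp))
  val_by_sensor <- lapply(sessions, function(s) s$samples$glucose_mgdl)
  base_m <- minute_index(base$timestamp)

  prof <- lapply(shifts, function(k) {
    ards <- rep(NA_real_, nrow(base))
    for (i in seq_len(nrow(base))) {
      sm <- samp_by_sensor[[base$sensor_id[i]]]
      target <- base_m[i] + k
      ok <- which(sm <= target & sm >= target - window_min)
      if (!length(ok)) next
      sv <- val_by_sensor[[base$sensor_id[i]]][ok[length(ok)]]
      ards[i] <- abs(base$reference_mgdl[i] - sv) / base$reference_mgdl[i] * 100
    }
    n <- sum(!is.na(ards))
    data.frame(shift = k, mard = if (n) mean(ards, na.rm = TRUE) else NA_real_, n = n)
  })
  prof <- do.call(rbind, prof)
  prof <- prof[!is.na(prof$mard), , drop = FALSE]
  rownames(prof) <- NULL
  if (!nrow(prof)) stop("no shift produced any pairing", call. = FALSE)
  structure(list(profile = prof,
                 argmin_shift = prof$shift[which.min(prof$mard)],
                 mard0 = if (0 %in% prof$shift) prof$mard[prof$shift == 0] else NA_real_),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  cat("<lag_profile>", nrow(x$profile), "shifts evaluated\n")
  cat(sprintf("  MARD minimized at shift %d min (MARD %.2f %%)\n",
              x$argmin_shift, min(x$profile$mard)))
  if (!is.na(x$mard0)) cat(sprintf("  unshifted MARD %.2f %%\n", x$mard0))
  invisible(x)
}

#' @export
plot.lag_profile <- function(x, ...) {
  graphics::plot(x$profile$shift, x$profile$mard, type = "b",
                 xlab = "Reference time shift (min)", ylab = "MARD (%)", ...)
  graphics::abline(v = x$argmin_shift, lty = 2, col = "grey50")
  invisible(x)
}
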