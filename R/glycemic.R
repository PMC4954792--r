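#' Dysglycemia band of a glucose value
#'
#' Bands (mg/dl, closed integer edges as conventionally printed):
#' severe hypoglycemia <= 40, moderate hypoglycemia 41-70, euglycemia
#' 71-149, moderate hyperglycemia 150-179, severe hyperglycemia > 179.
#' Non-integer values fall in the band whose continuous interval
#' `(40,70], (70,149], (149,179]` contains them. The insulin-therapy target
#' band (80-149 mg/dl) is a separate labelled range, never mixed with these
#' analysis bands; see [glycemic_bands()].
#'
#' @param value numeric vector of glucose values (mg/dl, positive).
#' @return character vector of band names.
#' @export
classify_band <- function(value) {
  if (any(!is.finite(value) | value <= 0)) {
    stop("glucose values must be positive and finite", call. = FALSE)
  }
  as.character(cut(value, breaks = c(0, 40, 70, 149, 179, Inf),
                   labels = c("severe_hypo", "moderate_hypo", "euglycemia",
                              "moderate_hyper", "severe_hyper"),
                   right = TRUE))
}

#' The analysis band edges and insulin target range
#'
#' @return list with the band upper edges (mg/dl) and the insulin-therapy
#'   target range (80-149 mg/dl), which is distinct from the 71-149
#'   euglycemia analysis band.
#' @export
glycemic_bands <- function() {
  list(severe_hypo_max = 40, moderate_hypo_max = 70, euglycemia_max = 149,
       moderate_hyper_max = 179, insulin_target = c(80, 149),
       analysis_target = c(71, 149))
}

#' Count newly developed in-band events
#'
#' An event is counted at each transition from outside the band into it; a
#' series that starts inside the band contributes one event for the initial
#' episode. Consecutive in-band readings belong to one event, so densely
#' sampled series are not over-counted.
#'
#' @param values time-ordered numeric vector of glucose values.
#' @param in_band either a logical vector (same length) or a predicate
#'   function mapping values to logical.
#' @return integer event count.
#' @export
count_events <- function(values, in_band) {
  flags <- if (is.function(in_band)) in_band(values) else as.logical(in_band)
  stopifnot(length(flags) == length(values))
  if (!length(flags)) return(0L)
  sum(diff(c(FALSE, flags)) == 1L)
}

#' Time shares below, in, and above a glucose target range
#'
#' With `method = "interpolated"` (default) the trajectory between
#' consecutive samples is taken as linear and the share of time in each
#' range is computed from the interpolated path, including exact
#' band-edge crossing times; segments lying exactly on an edge count toward
#' the target range (edges are inclusive). With `method = "readings"` the
#' share of readings in each range is returned instead (the natural choice
#' when interpolation between sparse draws is not wanted); both views are
#' useful for intermittent 2-4-h reference data and they coincide in the
#' dense-sampling limit.
#'
#' @param timestamps time-ordered POSIXct (or numeric minutes).
#' @param values glucose values (mg/dl) at `timestamps`.
#' @param target length-2 range, default the 71-149 mg/dl analysis target.
#' @param method `"interpolated"` or `"readings"`.
#' @return named numeric vector (percent): `below`, `target`, `above`;
#'   sums to 100.
#' @export
time_in_ranges <- function(timestamps, values, target = c(71, 149),
                           method = c("interpolated", "readings")) {
  method <- match.arg(method)
  stopifnot(length(timestamps) == length(values), target[1] < target[2])
  if (method == "readings") {
    below <- mean(values < target[1]) * 100
    above <- mean(values > target[2]) * 100
    return(c(below = below, target = 100 - below - above, above = above))
  }
  if (length(values) < 2) {
    stop("interpolated time in range needs at least 2 samples", call. = FALSE)
  }
  t <- if (inherits(timestamps, "POSIXct")) as.numeric(timestamps) / 60 else as.numeric(timestamps)
  ord <- order(t)
  t <- t[ord]; v <- values[ord]
  total <- t[length(t)] - t[1]
  if (total <= 0) stop("zero total time span", call. = FALSE)
  # time with v <= c along the piecewise-linear path
  time_le <- function(c) {
    t0 <- t[-length(t)]; t1 <- t[-1]
    v0 <- v[-length(v)]; v1 <- v[-1]
    dt <- t1 - t0
    lo <- pmin(v0, v1); hi <- pmax(v0, v1)
    frac <- ifelse(hi <= c, 1,
            ifelse(lo > c, 0, (c - lo) / (hi - lo)))
    sum(dt * frac)
  }
  # time strictly above upper edge / strictly below lower edge; segments
  # resting exactly on an edge have hi == c resp. lo == c and count as target
  above <- (total - time_le(target[2])) / total * 100
  time_ge <- function(c) {
    t0 <- t[-length(t)]; t1 <- t[-1]
    v0 <- v[-length(v)]; v1 <- v[-1]
    dt <- t1 - t0
    lo <- pmin(v0, v1); hi <- pmax(v0, v1)
    frac <- ifelse(lo >= c, 1,
            ifelse(hi < c, 0, (hi - c) / (hi - lo)))
    sum(dt * frac)
  }
  below <- (total - time_ge(target[1])) / total * 100
  c(below = below, target = 100 - below - above, above = above)
}

#' Glycemic variability: standard deviation and glycemic lability index
#'
#' The glycemic lability index (GLI) is the sum over consecutive readings of
#' the squared glucose change divided by the elapsed time in hours,
#' accumulated per 24-h window and averaged across windows; windows are
#' anchored at the first sample and partial windows are scaled up to 24 h.
#' Units: (mg/dl)^2 / h per 24 h. Each squared-change increment is assigned
#' to the window containing the start of its interval.
#'
#' @param timestamps time-ordered POSIXct (or numeric minutes).
#' @param values glucose values (mg/dl).
#' @param window_hours window length for GLI accumulation (default 24).
#' @return list with `sd` (mg/dl), `gli` (average per-window GLI) and
#'   `gli_windows` (per-window values after scaling).
#' @export
glycemic_variability <- function(timestamps, values, window_hours = 24) {
  stopifnot(length(timestamps) == length(values))
  t <- if (inherits(timestamps, "POSIXct")) as.numeric(timestamps) / 60 else as.numeric(timestamps)
  ord <- order(t)
  t <- t[ord]; v <- values[ord]
  s <- if (length(v) >= 2) stats::sd(v) else NA_real_
  if (length(v) < 2) {
    return(list(sd = s, gli = NA_real_, gli_windows = numeric(0)))
  }
  dt_h <- diff(t) / 60
  if (any(dt_h <= 0)) stop("duplicate or unordered timestamps", call. = FALSE)
  contrib <- diff(v)^2 / dt_h
  w_min <- window_hours * 60
  win <- floor((t[-length(t)] - t[1]) / w_min)  # window of the interval start
  tot <- tapply(contrib, win, sum)
  # minutes of data span covered inside each window, for partial-window scaling
  span_end <- t[length(t)]
  covered <- vapply(as.numeric(names(tot)), function(w) {
    min(span_end, t[1] + (w + 1) * w_min) - max(t[1], t[1] + w * w_min)
  }, 0)
  scaled <- as.numeric(tot) * (w_min / covered)
  list(sd = s, gli = mean(scaled), gli_windows = scaled)
}

#' Summarise a glucose series
#'
#' One-stop glycemic summary of an intermittent or continuous series:
#' number of readings, mean, SD, glycemic lability index, time shares
#' around the target range, extremes, and counts of newly developed
#' hypoglycemic (< 71 mg/dl) and hyperglycemic (> 149 mg/dl) events plus
#' per-band event counts.
#'
#' @param timestamps time-ordered POSIXct (or numeric minutes).
#' @param values glucose values (mg/dl).
#' @param target target range, default 71-149 mg/dl.
#' @param tir_method time-in-range method, see [time_in_ranges()].
#' @return object of class `glycemic_summary` (a named list).
#' @export
glycemic_summary <- function(timestamps, values, target = c(71, 149),
                             tir_method = "interpolated") {
  stopifnot(length(timestamps) == length(values), length(values) >= 1)
  ord <- order(as.numeric(timestamps))
  timestamps <- timestamps[ord]; values <- values[ord]
  tir <- if (length(values) >= 2 || tir_method == "readings") {
    time_in_ranges(timestamps, values, target, tir_method)
  } else c(below = NA_real_, target = NA_real_, above = NA_real_)
  vb <- glycemic_variability(timestamps, values)
  bands <- c("severe_hypo", "moderate_hypo", "euglycemia", "moderate_hyper",
             "severe_hyper")
  band_of <- classify_band(values)
  band_events <- vapply(bands, function(b) count_events(values, band_of == b), 0L)
  structure(list(
    n_readings = length(values),
    mean = mean(values), sd = vb$sd, gli = vb$gli,
    time_in_target_pct = unname(tir["target"]),
    time_below_target_pct = unname(tir["below"]),
    time_above_target_pct = unname(tir["above"]),
    min = min(values), max = max(values),
    events_hypo = count_events(values, values < target[1]),
    events_hyper = count_events(values, values > target[2]),
    band_events = band_events,
    target = target
  ), class = "glycemic_summary")
}

#' @export
print.glycemic_summary <- function(x, ...) {
  cat("<glycemic_summary>", x$n_readings, "readings\n")
  cat(sprintf("  mean %.1f, SD %.1f, min %.0f, max %.0f mg/dl; GLI %.1f (mg/dl)^2/h per 24 h\n",
              x$mean, x$sd, x$min, x$max, x$gli))
  cat(sprintf("  time <%d: %.1f %%, in %d-%d: %.1f %%, >%d: %.1f %%\n",
              x$target[1], x$time_below_target_pct, x$target[1], x$target[2],
              x$time_in_target_pct, x$target[2], x$time_above_target_pct))
  cat(sprintf("  newly developed events: hypo %d, hyper %d\n",
              x$events_hypo, x$events_hyper))
  invisible(x)
}
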