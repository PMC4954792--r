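# Shared fixture builders: tiny datasets and sessions constructed in code.

t0 <- as.POSIXct("2014-03-01 00:00:00", tz = "UTC")

min_at <- function(m) t0 + m * 60

# minutes since the fixture origin, robust to difftime unit guessing
mins_of <- function(ts) (as.numeric(ts) - as.numeric(t0)) / 60

# Build a cgm_dataset for one sensor from a vector of displayed minutes and
# values, plus optional reference and calibration minute/value vectors.
make_dataset <- function(sample_min, sample_val,
                         ref_min = numeric(0), ref_val = numeric(0),
                         cal_min = numeric(0), cal_val = numeric(0),
                         init_min = 0, removal_min = max(sample_min) + 1,
                         removal_cause = NA, patient_id = "P01",
                         sensor_id = "P01S1", ref_source = "arterial",
                         gap_causes = NULL) {
  cgm_dataset(
    cgm = data.frame(patient_id = patient_id, sensor_id = sensor_id,
                     timestamp = min_at(sample_min), glucose_mgdl = sample_val),
    reference = if (length(ref_min)) {
      data.frame(patient_id = patient_id, timestamp = min_at(ref_min),
                 glucose_mgdl = ref_val,
                 source = rep_len(ref_source, length(ref_min)))
    } else {
      data.frame(patient_id = character(0), timestamp = min_at(numeric(0)),
                 glucose_mgdl = numeric(0), source = character(0))
    },
    calibrations = if (length(cal_min)) {
      data.frame(patient_id = patient_id, sensor_id = sensor_id,
                 timestamp = min_at(cal_min), reference_mgdl = cal_val)
    } else {
      data.frame(patient_id = character(0), sensor_id = character(0),
                 timestamp = min_at(numeric(0)), reference_mgdl = numeric(0))
    },
    sessions = data.frame(patient_id = patient_id, sensor_id = sensor_id,
                          init_time = min_at(init_min),
                          removal_time = min_at(removal_min),
                          removal_cause = removal_cause),
    gap_causes = gap_causes
  )
}

make_session <- function(...) sensor_sessions(make_dataset(...))[[1]]

# Pairs table built directly from reference/sensor value vectors (for the
# point-accuracy statistics, which do not need the pairing machinery).
make_pairs <- function(reference, sensor, patient_id = "P01") {
  if (!length(reference)) {
    return(data.frame(patient_id = character(0), sensor_id = character(0),
                      timestamp = min_at(numeric(0)),
                      reference_mgdl = numeric(0), sensor_mgdl = numeric(0),
                      ard_pct = numeric(0), source = character(0),
                      is_calibration = logical(0), sensor_age_min = numeric(0)))
  }
  data.frame(patient_id = rep_len(patient_id, length(reference)),
             sensor_id = "S1", timestamp = min_at(seq_along(reference) * 120),
             reference_mgdl = reference, sensor_mgdl = sensor,
             ard_pct = abs(reference - sensor) / reference * 100,
             source = "arterial", is_calibration = FALSE, sensor_age_min = 0,
             stringsAsFactors = FALSE)
}

# Small quick cohort for pipeline-level tests; dots override the defaults.
quick_config <- function(...) {
  args <- list(n_patients = 4, pre_hours = 24, post_hours = 24)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Per-patient lag-profile argmins under a controlled recovery design.
# A first-order lag equals a pure delay of tau only for locally linear
# input, so the experiment isolates the delay: smooth sustained trends
# (slow mean reversion, strong smoothing, no transient episode bumps whose
# curvature biases the optimum low), full 72-h sessions, dense reference
# draws, no display gaps, and no gain drift or re-calibration (anchoring
# the gain to blood mid-trend partially cancels the lag and would mask it).
recovery_argmins <- function(tau, seed, n_patients = 20, noise = 1) {
  co <- simulate_cohort(sim_config(
    n_patients = n_patients, seed = seed, lag_min = tau,
    mean_reversion_hours = 4, bg_smoothing_min = 90,
    episode_rate_per_day = 0, sensor_noise_sd = noise,
    drift_sd_per_hour = 0, calibration_every_hours = 1e6,
    gap_rate_per_hour = 0, premature_removal_prob = 0,
    reference_interval_hours = c(0.5, 1),
    pre_hours = 0, post_hours = 0))
  ds <- co$dataset
  vapply(unique(ds$sessions$patient_id), function(p) {
    sub <- structure(list(
      cgm = ds$cgm[ds$cgm$patient_id == p, ],
      reference = ds$reference[ds$reference$patient_id == p, ],
      calibrations = ds$calibrations[ds$calibrations$patient_id == p, ],
      sessions = ds$sessions[ds$sessions$patient_id == p, ],
      covariates = NULL, gap_causes = NULL), class = "cgm_dataset")
    tryCatch(time_shift_mard(sub)$argmin_shift, error = function(e) NA_real_)
  }, 0)
}

# Independently written Clarke zone oracle: per-point, ordered predicate
# checks transcribed separately from the vectorised implementation.
clarke_oracle <- function(x, y) {
  stopifnot(length(x) == 1, length(y) == 1)
  in_a <- function() (x < 70 && y < 70) || (abs(y - x) <= 0.2 * x)
  in_e <- function() (x <= 70 && y >= 180) || (x >= 180 && y <= 70)
  in_c <- function() {
    upper <- (x >= 70 && x <= 290) && (y >= x + 110)
    lower <- (x >= 130 && x <= 180) && (y <= 1.4 * x - 182)
    upper || lower
  }
  in_d <- function() {
    right <- x >= 240 && (y >= 70 && y <= 180)
    left1 <- x <= 175 / 3 && (y >= 70 && y <= 180)
    left2 <- (x >= 175 / 3 && x <= 70) && y >= 1.2 * x
    right || left1 || left2
  }
  if (in_a()) return("A")
  if (in_e()) return("E")
  if (in_c()) return("C")
  if (in_d()) return("D")
  "B"
}
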