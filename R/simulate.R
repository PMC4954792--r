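# Synthetic ICU-CGM cohort generator.
#
# Emulates the statistical structure the evaluation pipeline assumes:
# mean-reverting within-patient blood glucose dynamics, a first-order
# interstitial diffusion lag, a per-minute sensor with multiplicative
# calibration-anchored gain drift and additive noise, stochastic display
# gaps in four duration categories, premature sensor removals, intermittent
# reference sampling at blood-gas cadence, and the standard calibration
# schedule (start, +1 h, +2 h, then every 8 h, plus a fresh entry after
# every display gap > 15 min). All randomness is a pure function of the
# seed. The default parameter values are calibration targets taken from the
# cohort the package is designed to analyse (see the sim_config()
# documentation for the provenance of each default); they are not claims of
# physiological fidelity.

#' Simulation configuration
#'
#' Every generative parameter of [simulate_cohort()], with defaults chosen
#' as calibration targets for a realistic medical-surgical ICU cohort:
#'
#' @param n_patients number of patients (default 20).
#' @param seed integer seed; together with the other fields it fully
#'   determines the generated cohort.
#' @param bg_mean stationary mean of the latent blood glucose process
#'   (mg/dl; default 134, matching a typical ICU per-patient mean under
#'   moderate insulin control).
#' @param bg_sd stationary within-patient SD of blood glucose (mg/dl;
#'   default 25).
#' @param mean_reversion_hours time constant of mean reversion of the
#'   Ornstein-Uhlenbeck glucose dynamics (h; default 2: excursions decay on
#'   the scale of a couple of hours).
#' @param lag_min interstitial diffusion lag time constant tau (min;
#'   default 10, the upper end of the physiological delay usually reported
#'   for subcutaneous sensors).
#' @param sensor_noise_sd additive per-minute sensor noise SD (mg/dl;
#'   default 8).
#' @param drift_sd_per_hour SD of the sensor gain's multiplicative random
#'   walk per hour (default 0.01); the gain re-anchors at every
#'   calibration, so calibrating during a steep excursion bakes the
#'   momentary blood/interstitial discrepancy into the gain.
#' @param reference_interval_hours range of the uniform waiting time
#'   between blood-gas reference draws (h; default 2-4, routine ICU
#'   cadence).
#' @param reference_noise_sd SD of the reference (blood gas analyzer)
#'   measurement error (mg/dl; default 0: the reference is treated as the
#'   gold standard).
#' @param calibration_every_hours interval of routine calibrations after
#'   the +2 h entry (default 8).
#' @param gap_rate_per_hour Poisson rate of display-gap onsets (default
#'   0.12/h, about one gap per 8 h of monitoring).
#' @param gap_category_probs mixture weights of the four gap duration
#'   categories very_brief/brief/prolonged/very_prolonged (default
#'   0.439/0.226/0.174/0.161, the observed category shares in the cohort
#'   this emulates); durations are uniform within category (2-14, 15-30,
#'   31-120, 121-300 min).
#' @param gap_cause_probs sampling weights of gap cause codes 1-7 (codes
#'   1-3 device-related).
#' @param premature_removal_prob probability that a sensor is removed
#'   before 72 h (default 0.677, i.e. about 21 of 31 sensors).
#' @param premature_range_hours range of the uniform premature removal
#'   time (default 6-66 h).
#' @param removal_cause_probs sampling weights of removal cause codes 1-7
#'   for premature removals.
#' @param second_sensor_prob probability that a patient receives a second
#'   sensor after a premature first removal (default 0.8, so a 20-patient
#'   cohort carries about 31 sensors and about 21 premature removals in
#'   expectation).
#' @param session_hours nominal sensor lifetime (default 72).
#' @param pre_hours,post_hours reference-only monitoring before the first
#'   sensor and after the last removal (default 72 each, supporting the
#'   longitudinal before/during/after comparison).
#' @param episode_rate_per_day rate of superimposed dysglycemia episodes
#'   (default 0.5/day; transient excursions on top of the mean-reverting
#'   baseline, biased toward hyperglycemia as in stress hyperglycemia).
#' @param episode_amp_mean,episode_amp_sd amplitude distribution of the
#'   episodes (mg/dl; default 55 +/- 20).
#' @param episode_hyper_prob probability that an episode is hyperglycemic
#'   (vs hypoglycemic; default 0.8).
#' @param covariate_coupling strength of the coupling between the SOFA
#'   covariate and sensor noise (default 0: covariates carry no signal;
#'   set > 0 to create a recoverable confounder effect).
#' @param bg_smoothing_min stage time constant of the two-stage smoother
#'   applied to the latent glucose dynamics (minutes; see
#'   [simulate_blood_glucose()]).
#' @return object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_patients = 20, seed = 1, bg_mean = 134, bg_sd = 25,
                       mean_reversion_hours = 2, lag_min = 10,
                       sensor_noise_sd = 8, drift_sd_per_hour = 0.01,
                       reference_interval_hours = c(2, 4),
                       reference_noise_sd = 0,
                       calibration_every_hours = 8,
                       gap_rate_per_hour = 0.12,
                       gap_category_probs = c(very_brief = 0.439, brief = 0.226,
                                              prolonged = 0.174,
                                              very_prolonged = 0.161),
                       gap_cause_probs = c(0.233, 0.150, 0.109, 0.156, 0.034,
                                           0.278, 0.040),
                       premature_removal_prob = 0.677,
                       premature_range_hours = c(6, 66),
                       removal_cause_probs = c(7, 7, 1, 1, 1, 2, 2) / 21,
                       second_sensor_prob = 0.8,
                       session_hours = 72, pre_hours = 72, post_hours = 72,
                       episode_rate_per_day = 0.5, episode_amp_mean = 55,
                       episode_amp_sd = 20, episode_hyper_prob = 0.8,
                       covariate_coupling = 0, bg_smoothing_min = 30) {
  cfg <- as.list(environment())
  if (bg_mean <= 0) stop("bg_mean must be positive", call. = FALSE)
  if (lag_min < 0) stop("lag_min must be >= 0", call. = FALSE)
  stopifnot(n_patients >= 1, bg_sd >= 0, sensor_noise_sd >= 0,
            drift_sd_per_hour >= 0, gap_rate_per_hour >= 0,
            premature_removal_prob >= 0, premature_removal_prob <= 1,
            length(gap_category_probs) == 4,
            abs(sum(gap_category_probs) - 1) < 1e-6)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d patients, seed %d\n", x$n_patients, x$seed))
  cat(sprintf("  glucose OU: mean %g mg/dl, SD %g, reversion %g h; episodes %g/day\n",
              x$bg_mean, x$bg_sd, x$mean_reversion_hours, x$episode_rate_per_day))
  cat(sprintf("  sensor: lag tau %g min, noise SD %g mg/dl, gain drift %g/h\n",
              x$lag_min, x$sensor_noise_sd, x$drift_sd_per_hour))
  cat(sprintf("  gaps %g/h (%s), premature removal p %g, second sensor p %g\n",
              x$gap_rate_per_hour,
              paste(sprintf("%.0f%%", 100 * x$gap_category_probs), collapse = "/"),
              x$premature_removal_prob, x$second_sensor_prob))
  invisible(x)
}

#' Simulate a latent blood-glucose path on the 1-minute grid
#'
#' Mean-reverting dynamics with stationary mean `bg_mean` and stationary SD
#' `bg_sd`: an exactly discretized Ornstein-Uhlenbeck process on the
#' 1-minute grid (`rho = exp(-1/theta)` per minute, `theta` the
#' mean-reversion time) passed through a two-stage exponential smoother
#' (stage time constant `smoothing_min`, default 30 min). A raw OU path has
#' independent minute-to-minute increments -- a roughness physiological
#' glucose does not have at the minute scale, and one that would make the
#' interstitial diffusion delay ill-posed to recover (for a random-walk
#' signal the error-minimizing shift of a first-order lag is the kernel
#' median `0.69 tau`, not `tau`). Two smoothing stages make the path's
#' velocity continuous as well, so excursions have the momentum of real
#' meal- and insulin-driven dynamics and the lag analysis sees locally
#' linear trends. The OU innovation variance is rescaled via the exact
#' discrete-time Lyapunov solution so the smoothed path's stationary SD
#' equals `bg_sd`. Optional transient dysglycemia episodes (half-sine
#' bumps) are superimposed, and the path is floored at 20 mg/dl. Uses the
#' current RNG state; seed through [simulate_cohort()] or an explicit
#' `set.seed()`.
#'
#' @param config a `sim_config`.
#' @param n_minutes path length.
#' @param smoothing_min time constant of the smoothing filter (minutes;
#'   0 disables smoothing and yields the raw OU path).
#' @return numeric vector of length `n_minutes` (mg/dl).
#' @export
simulate_blood_glucose <- function(config, n_minutes,
                                   smoothing_min = config$bg_smoothing_min) {
  stopifnot(inherits(config, "sim_config"), n_minutes >= 1, smoothing_min >= 0)
  mu <- config$bg_mean
  theta <- config$mean_reversion_hours * 60
  rho <- exp(-1 / theta)
  if (config$bg_sd == 0) {
    x <- rep(0, n_minutes)
  } else if (smoothing_min == 0) {
    sigma <- config$bg_sd
    x <- numeric(n_minutes)
    x[1] <- sigma * stats::rnorm(1)
    if (n_minutes > 1) {
      z <- stats::rnorm(n_minutes - 1, sd = sigma * sqrt(1 - rho^2))
      for (t in 2:n_minutes) x[t] <- x[t - 1] * rho + z[t - 1]
    }
  } else {
    # state: (OU driver, stage-1 smooth, stage-2 smooth); innovation variance
    # is scaled via the exact discrete-time Lyapunov solution so the output's
    # stationary SD equals bg_sd
    b <- exp(-1 / smoothing_min)
    A <- matrix(c(rho, 0, 0,
                  (1 - b) * rho, b, 0,
                  (1 - b)^2 * rho, (1 - b) * b, b), 3, 3, byrow = TRUE)
    B <- c(1, 1 - b, (1 - b)^2)
    P <- matrix(solve(diag(9) - kronecker(A, A), as.vector(B %o% B)), 3, 3)
    q <- config$bg_sd^2 / P[3, 3]
    z0 <- stats::rnorm(1)
    state <- z0 * sqrt(diag(P * q))  # common stationary-scale start
    x <- numeric(n_minutes)
    x[1] <- state[3]
    if (n_minutes > 1) {
      e <- stats::rnorm(n_minutes - 1, sd = sqrt(q))
      for (t in 2:n_minutes) {
        state <- c(A %*% state) + B * e[t - 1]
        x[t] <- state[3]
      }
    }
  }
  g <- mu + x
  # superimposed dysglycemia episodes: half-sine excursions
  n_ep <- stats::rpois(1, config$episode_rate_per_day * n_minutes / 1440)
  if (n_ep > 0) {
    for (i in seq_len(n_ep)) {
      start <- stats::runif(1, 1, n_minutes)
      dur <- max(60, stats::rnorm(1, 180, 60))
      amp <- max(10, stats::rnorm(1, config$episode_amp_mean, config$episode_amp_sd))
      sgn <- if (stats::runif(1) < config$episode_hyper_prob) 1 else -1
      idx <- seq(floor(start), min(n_minutes, floor(start + dur)))
      phase <- (idx - start) / dur
      g[idx] <- g[idx] + sgn * amp * sin(pi * pmin(1, pmax(0, phase)))
    }
  }
  pmax(g, 20)
}

#' First-order interstitial lag filter
#'
#' Discretizes the diffusion equation `dI/dt = (G - I) / tau` on the
#' 1-minute grid with the exact exponential update
#' `I[t] = G[t] + (I[t-1] - G[t]) * exp(-1/tau)`, so that a step change in
#' blood glucose reaches `1 - exp(-1)` (63.2 %) of its height after `tau`
#' minutes. `tau = 0` returns the blood path unchanged.
#'
#' @param blood_path numeric vector, blood glucose on the 1-minute grid.
#' @param tau lag time constant (minutes, >= 0).
#' @return numeric vector, interstitial glucose on the same grid.
#' @export
simulate_interstitial <- function(blood_path, tau) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (tau == 0 || length(blood_path) < 2) return(blood_path)
  a <- exp(-1 / tau)
  i <- numeric(length(blood_path))
  i[1] <- blood_path[1]
  for (t in 2:length(blood_path)) {
    i[t] <- blood_path[t] + (i[t - 1] - blood_path[t]) * a
  }
  i
}

# Draw gap onsets/durations for a session of `n_minutes`; returns a
# data.frame(start, duration, cause) in session-relative minutes. Gaps are
# non-overlapping; onsets form a Poisson process thinned by overlap.
#' @noRd
.draw_gaps <- function(config, n_minutes) {
  n_cand <- stats::rpois(1, config$gap_rate_per_hour * n_minutes / 60)
  if (n_cand == 0) {
    return(data.frame(start = numeric(0), duration = numeric(0),
                      cause = integer(0)))
  }
  starts <- sort(floor(stats::runif(n_cand, 2, n_minutes)))
  cat_lo <- c(2, 15, 31, 121)
  cat_hi <- c(14, 30, 120, 300)
  cats <- sample(1:4, n_cand, replace = TRUE, prob = config$gap_category_probs)
  durs <- floor(stats::runif(n_cand, cat_lo[cats], cat_hi[cats] + 1))
  causes <- sample(1:7, n_cand, replace = TRUE, prob = config$gap_cause_probs)
  keep <- logical(n_cand)
  last_end <- -1
  for (i in seq_len(n_cand)) {
    if (starts[i] > last_end + 1 && starts[i] + durs[i] - 1 < n_minutes - 1) {
      keep[i] <- TRUE
      last_end <- starts[i] + durs[i] - 1
    }
  }
  data.frame(start = starts[keep], duration = durs[keep],
             cause = causes[keep])
}

#' Simulate a sensor session over an interstitial path
#'
#' Applies the observation model: displayed value =
#' `gain(t) * interstitial(t) + noise`, where the gain performs a
#' multiplicative random walk and re-anchors at every calibration so the
#' display matches the entered reference exactly at the calibration minute
#' (which is how calibrating during a steep excursion propagates error);
#' carves display gaps from the configured gap process; and truncates the
#' session at the (possibly premature) removal time. Calibrations follow
#' the standard schedule (start, +1 h, +2 h, then every
#' `calibration_every_hours`) plus one after every display gap longer than
#' 15 min. Uses the current RNG state.
#'
#' @param interstitial numeric vector, interstitial glucose on the session's
#'   1-minute grid (session-relative minute 0 = first displayed minute).
#' @param blood numeric vector, the matching blood path (calibration entries
#'   and reference draws read this path).
#' @param config a `sim_config`.
#' @param removal_min session length in minutes (monitoring is minutes
#'   `0 .. removal_min - 1`); defaults to the full path length.
#' @return list with `display` (data.frame `minute`, `value` of displayed
#'   minutes), `calibrations` (data.frame `minute`, `reference`, scheduled
#'   and post-gap), `gaps` (data.frame `start`, `duration`, `cause`),
#'   `removal_min`.
#' @export
simulate_sensor <- function(interstitial, blood, config,
                            removal_min = length(interstitial)) {
  stopifnot(inherits(config, "sim_config"),
            length(interstitial) >= removal_min, removal_min >= 1)
  n <- removal_min
  gaps <- .draw_gaps(config, n)
  gap_mask <- rep(FALSE, n)
  for (i in seq_len(nrow(gaps))) {
    gap_mask[(gaps$start[i] + 1):(gaps$start[i] + gaps$duration[i])] <- TRUE
  }

  # calibration minutes: schedule + first displayed minute after >15-min gaps
  sched <- c(0, 60, 120)
  nxt <- 120 + config$calibration_every_hours * 60
  while (nxt < n) {
    sched <- c(sched, nxt)
    nxt <- nxt + config$calibration_every_hours * 60
  }
  post_gap <- integer(0)
  for (i in seq_len(nrow(gaps))) {
    if (gaps$duration[i] > 15) {
      m <- gaps$start[i] + gaps$duration[i]
      while (m < n && gap_mask[m + 1]) m <- m + 1
      if (m < n) post_gap <- c(post_gap, m)
    }
  }
  # displace scheduled calibrations that land inside a gap to the next
  # displayed minute (a calibration needs a live display to be entered)
  cal_min <- sort(unique(c(vapply(sched, function(m) {
    while (m < n && gap_mask[m + 1]) m <- m + 1
    m
  }, 0), post_gap)))
  cal_min <- cal_min[cal_min < n & !gap_mask[cal_min + 1]]

  ref_noise <- if (config$reference_noise_sd > 0) {
    stats::rnorm(length(cal_min), sd = config$reference_noise_sd)
  } else rep(0, length(cal_min))
  cal_ref <- pmax(20, blood[cal_min + 1] + ref_noise)

  # gain path: random walk in log-gain, re-anchored at each calibration.
  # The entered blood value recalibrates *subsequent* output: the displayed
  # value at the calibration minute itself still carries the old gain (it is
  # the value the entry gets compared against).
  gain <- rep(1, n)
  step_sd <- config$drift_sd_per_hour / sqrt(60)
  incr <- if (step_sd > 0) stats::rnorm(n, sd = step_sd) else rep(0, n)
  cal_set <- cal_min + 1
  log_g <- 0
  for (t in seq_len(n)) {
    gain[t] <- exp(log_g)
    if (t %in% cal_set) {
      log_g <- log(cal_ref[match(t, cal_set)] / interstitial[t])
    } else {
      log_g <- log_g + incr[t]
    }
  }

  noise <- if (config$sensor_noise_sd > 0) {
    stats::rnorm(n, sd = config$sensor_noise_sd)
  } else rep(0, n)
  value <- pmax(20, gain * interstitial[seq_len(n)] + noise)

  minutes <- which(!gap_mask) - 1
  list(display = data.frame(minute = minutes, value = value[minutes + 1]),
       calibrations = data.frame(minute = cal_min, reference = cal_ref),
       gaps = gaps, removal_min = n)
}

#' Generate a complete synthetic ICU-CGM cohort
#'
#' Produces a [cgm_dataset()] (per-minute sensor traces, intermittent
#' arterial/venous reference log, calibration log, session records,
#' covariates, gap-cause annotations) plus a truth bundle holding the
#' latent blood and interstitial paths, the configured lag, and the
#' injected gap list per sensor -- everything needed to test each pipeline
#' stage against known ground truth. The output is a pure function of the
#' configuration (including its seed).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `dataset`
#'   (a `cgm_dataset`) and `truth` (per-patient list: `blood`,
#'   `interstitial`, `tau`, `sessions` with injected gaps and removal
#'   minutes, and the patient's absolute start minute).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_cohort_impl(config))
}

#' @noRd
.simulate_cohort_impl <- function(config) {
  origin_min <- minute_index(as_minute("2014-03-01T00:00:00"))
  cgm_rows <- list(); ref_rows <- list(); cal_rows <- list()
  ses_rows <- list(); cov_rows <- list(); gapc_rows <- list()
  truth <- list()

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    has_diabetes <- stats::runif(1) < 0.25
    has_vaso <- stats::runif(1) < 0.35

    # sensor session plan: first sensor after the pre window; optional second
    sess <- list()
    t_cursor <- config$pre_hours * 60
    for (s_i in 1:2) {
      premature <- stats::runif(1) < config$premature_removal_prob
      dur_min <- if (premature) {
        floor(stats::runif(1, config$premature_range_hours[1] * 60,
                           config$premature_range_hours[2] * 60))
      } else config$session_hours * 60
      cause <- if (premature) {
        sample(1:7, 1, prob = config$removal_cause_probs)
      } else NA_integer_
      sess[[s_i]] <- list(start = t_cursor, dur = dur_min, cause = cause)
      t_cursor <- t_cursor + dur_min + 60
      if (s_i == 2) break
      second <- premature && stats::runif(1) < config$second_sensor_prob
      if (!second) break
    }
    cgm_end <- sess[[length(sess)]]$start + sess[[length(sess)]]$dur
    total_min <- cgm_end + config$post_hours * 60 + 1

    blood <- simulate_blood_glucose(config, total_min)
    interstitial <- simulate_interstitial(blood, config$lag_min)

    # SOFA-coupled sensor noise (optional recoverable confounder)
    sofa0 <- max(0, round(stats::rnorm(1, 8, 3)))

    ses_truth <- list()
    for (s_i in seq_along(sess)) {
      sid <- sprintf("%sS%d", pid, s_i)
      st <- sess[[s_i]]
      idx <- (st$start + 1):(st$start + st$dur)
      cfg_s <- config
      if (config$covariate_coupling > 0) {
        cfg_s$sensor_noise_sd <- config$sensor_noise_sd *
          (1 + config$covariate_coupling * (sofa0 - 8) / 8)
      }
      sim <- simulate_sensor(interstitial[idx], blood[idx], cfg_s,
                             removal_min = st$dur)
      abs_min <- origin_min + st$start
      cgm_rows[[sid]] <- data.frame(
        patient_id = pid, sensor_id = sid,
        timestamp = minutes_to_posix(abs_min + sim$display$minute),
        glucose_mgdl = round(sim$display$value, 1), stringsAsFactors = FALSE)
      cal_rows[[sid]] <- data.frame(
        patient_id = pid, sensor_id = sid,
        timestamp = minutes_to_posix(abs_min + sim$calibrations$minute),
        reference_mgdl = round(sim$calibrations$reference, 1),
        stringsAsFactors = FALSE)
      ses_rows[[sid]] <- data.frame(
        patient_id = pid, sensor_id = sid,
        init_time = minutes_to_posix(abs_min),
        removal_time = minutes_to_posix(abs_min + sim$removal_min),
        removal_cause = st$cause, stringsAsFactors = FALSE)
      if (nrow(sim$gaps)) {
        gapc_rows[[sid]] <- data.frame(
          patient_id = pid, sensor_id = sid,
          start_time = minutes_to_posix(abs_min + sim$gaps$start),
          cause_code = sim$gaps$cause, stringsAsFactors = FALSE)
      }
      ses_truth[[sid]] <- list(start = st$start, removal_min = sim$removal_min,
                               gaps = sim$gaps)
    }

    # intermittent reference draws over the whole stay (pre + CGM + post);
    # calibration entries are blood draws too and join the reference log
    t <- floor(stats::runif(1, 0, 60))
    ref_min <- integer(0)
    while (t < total_min - 1) {
      ref_min <- c(ref_min, t)
      t <- t + floor(stats::runif(1, config$reference_interval_hours[1] * 60,
                                  config$reference_interval_hours[2] * 60 + 1))
    }
    cal_abs <- unlist(lapply(cal_rows[names(ses_truth)], function(df) {
      minute_index(df$timestamp) - origin_min
    }), use.names = FALSE)
    ref_min <- sort(unique(c(ref_min, cal_abs)))
    ref_noise <- if (config$reference_noise_sd > 0) {
      stats::rnorm(length(ref_min), sd = config$reference_noise_sd)
    } else rep(0, length(ref_min))
    src <- ifelse(stats::runif(length(ref_min)) < 0.893, "arterial", "venous")
    ref_rows[[pid]] <- data.frame(
      patient_id = pid, timestamp = minutes_to_posix(origin_min + ref_min),
      glucose_mgdl = round(pmax(20, blood[ref_min + 1] + ref_noise), 1),
      source = src, stringsAsFactors = FALSE)

    # covariates every 8 h at blood-gas cadence
    cov_min <- seq(0, total_min - 1, by = 480)
    k <- length(cov_min)
    ar1 <- function(mu, sd, phi = 0.8) {
      x <- numeric(k)
      x[1] <- stats::rnorm(1, mu, sd)
      for (j in seq_len(k - 1)) x[j + 1] <- mu + phi * (x[j] - mu) +
          stats::rnorm(1, 0, sd * sqrt(1 - phi^2))
      x
    }
    cov_list <- list(
      pO2 = ar1(90, 15), temperature = ar1(37.2, 0.6),
      hemoglobin = ar1(9.5, 1), potassium = ar1(4.2, 0.4),
      lactate = pmax(0.4, ar1(1.6, 0.8)), pH = ar1(7.4, 0.05),
      SOFA = pmax(0, round(ar1(sofa0, 1.5))),
      SIRS = rep(1, k), diabetes = rep(as.numeric(has_diabetes), k),
      vasopressor = rep(as.numeric(has_vaso), k))
    cov_rows[[pid]] <- do.call(rbind, lapply(names(cov_list), function(nm) {
      data.frame(patient_id = pid,
                 timestamp = minutes_to_posix(origin_min + cov_min),
                 name = nm, value = cov_list[[nm]], stringsAsFactors = FALSE)
    }))

    truth[[pid]] <- list(blood = blood, interstitial = interstitial,
                         tau = config$lag_min, start_min = origin_min,
                         sessions = ses_truth)
  }

  dataset <- cgm_dataset(
    cgm = do.call(rbind, cgm_rows),
    reference = do.call(rbind, ref_rows),
    calibrations = do.call(rbind, cal_rows),
    sessions = do.call(rbind, ses_rows),
    covariates = do.call(rbind, cov_rows),
    gap_causes = if (length(gapc_rows)) do.call(rbind, gapc_rows))
  structure(list(dataset = dataset, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n")
  print(x$dataset)
  invisible(x)
}
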