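test_that("the cohort is a pure function of the configuration seed", {
  a <- simulate_cohort(quick_config(seed = 123))
  b <- simulate_cohort(quick_config(seed = 123))
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(quick_config(seed = 124))
  expect_false(identical(a$dataset$cgm, c$dataset$cgm))

  # byte-identical files from the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cgm_dataset(a$dataset, d1)
  write_cgm_dataset(b$dataset, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_cohort(quick_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("zero process noise gives a constant latent path at the mean", {
  cfg <- sim_config(bg_sd = 0, episode_rate_per_day = 0)
  set.seed(1)
  g <- simulate_blood_glucose(cfg, 500)
  expect_equal(g, rep(134, 500))
})

test_that("the stationary SD of the latent path matches bg_sd within 10 %", {
  cfg <- sim_config(episode_rate_per_day = 0)
  set.seed(2024)
  sds <- replicate(50, sd(simulate_blood_glucose(cfg, 72 * 60)))
  expect_equal(mean(sds), 25, tolerance = 0.10)
})

test_that("the cohort-wide glucose mean sits near the configured 134 mg/dl", {
  co <- simulate_cohort(sim_config(seed = 2))
  expect_equal(mean(co$dataset$reference$glucose_mgdl), 134, tolerance = 0.08)
})

test_that("the interstitial filter has the first-order step response", {
  tau <- 20
  blood <- c(rep(100, 50), rep(150, 300))
  i <- simulate_interstitial(blood, tau)
  expect_equal(i[50], 100)
  # after tau minutes the response covers 1 - exp(-1) = 63.2 % of the step
  expect_equal(i[50 + tau], 100 + 50 * (1 - exp(-1)), tolerance = 1e-9)
  # and converges to the new level
  expect_equal(i[350], 150, tolerance = 0.01)

  expect_identical(simulate_interstitial(blood, 0), blood)
  expect_error(simulate_interstitial(blood, -1), ">= 0")
})

test_that("the interstitial filter attenuates a sinusoid by 1/sqrt(1+(w*tau)^2)", {
  tau <- 10
  period <- 240
  omega <- 2 * pi / period
  tt <- 0:(20 * period)
  blood <- 130 + 30 * sin(omega * tt)
  i <- simulate_interstitial(blood, tau)
  steady <- i[(5 * period):length(i)]
  amp <- (max(steady) - min(steady)) / 2
  expect_equal(amp, 30 / sqrt(1 + (omega * tau)^2), tolerance = 0.02)
})

test_that("a noiseless, lag-free, gap-free sensor reproduces the blood path", {
  co <- simulate_cohort(quick_config(
    seed = 15, lag_min = 0, sensor_noise_sd = 0, drift_sd_per_hour = 0,
    gap_rate_per_hour = 0))
  p <- extract_pairs(co$dataset)
  expect_gt(nrow(p), 0)
  expect_equal(p$sensor_mgdl, p$reference_mgdl)
  expect_equal(mard(p)$mard, 0)
})

test_that("premature removals and sensor counts match the configured rates", {
  removed <- 0; sensors <- 0
  for (s in 1:3) {
    co <- simulate_cohort(sim_config(seed = 300 + s))
    rel <- reliability_summary(co$dataset)
    sensors <- sensors + rel$cohort$n_sensors
    removed <- removed + rel$cohort$n_premature
  }
  # 3 cohorts of 20 patients: about 31 sensors and 21 premature removals each
  expect_equal(sensors / 3, 31, tolerance = 0.15)
  expect_equal(removed / 3, 21, tolerance = 0.2)
  expect_equal(removed / sensors, 0.677, tolerance = 0.15)
})

test_that("reference sampling lands near the 2-4-hourly blood-gas cadence", {
  co <- simulate_cohort(sim_config(seed = 4))
  ds <- co$dataset
  p <- extract_pairs(ds)
  per_patient <- table(p$patient_id)
  # comparative readings per monitored patient: of the order of 28
  expect_gt(median(per_patient), 15)
  expect_lt(median(per_patient), 45)
  gaps_h <- as.numeric(diff(ds$reference$timestamp[ds$reference$patient_id == "P01"]),
                       units = "hours")
  expect_true(all(gaps_h <= 4.2))
})

test_that("gap-free configuration yields full display of monitored time", {
  co <- simulate_cohort(quick_config(seed = 19, gap_rate_per_hour = 0))
  rel <- reliability_summary(co$dataset)
  expect_true(all(rel$per_sensor$pct_display_of_actual == 100))
  expect_equal(rel$cohort$n_gaps, 0)
})

test_that("MARD grows with sensor noise under paired seeds", {
  mards <- vapply(c(0, 4, 8, 16), function(s) {
    co <- simulate_cohort(quick_config(seed = 555, sensor_noise_sd = s))
    mard(extract_pairs(co$dataset))$mard
  }, 0)
  expect_true(all(diff(mards) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(bg_mean = -1), "bg_mean")
  expect_error(sim_config(lag_min = -2), "lag_min")
  expect_error(sim_config(gap_category_probs = c(0.5, 0.5, 0.2, 0.2)))
})
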