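test_that("glucose-range strata partition the pairs", {
  p <- make_pairs(c(120, 130, 140, 150), c(120, 130, 140, 150))
  sm <- mard_by_glucose_range(p)
  expect_equal(sm$strata$n, c(0, 4, 0))
  expect_equal(sm$strata$mard_median[2], 0)
  expect_true(is.na(sm$test$p))  # single non-empty stratum: no test

  set.seed(6)
  ref <- runif(200, 40, 300)
  p2 <- make_pairs(ref, ref * runif(200, 0.85, 1.15))
  sm2 <- mard_by_glucose_range(p2)
  expect_equal(sum(sm2$strata$n), nrow(p2))
  expect_equal(sm2$test$method, "kruskal_wallis")
})

test_that("proportional noise gives comparable MARD across glucose strata", {
  set.seed(33)
  ref <- runif(3000, 50, 300)
  sen <- ref * (1 + rnorm(3000, 0, 0.08))
  sm <- mard_by_glucose_range(make_pairs(ref, pmax(20, sen)))
  meds <- sm$strata$mard_median
  expect_lt(max(meds) - min(meds), 1.5)  # simulation error only
})

test_that("variability strata assign by distance from the daily reference mean", {
  # references exactly at the daily mean in a 2-value day -> both within 1 SD
  ds <- make_dataset(sample_min = 0:500, sample_val = rep(100, 501),
                     ref_min = c(100, 200), ref_val = c(100, 100),
                     removal_min = 501)
  p <- extract_pairs(ds)
  sm <- mard_by_variability(p, ds)
  expect_equal(sm$strata$n[sm$strata$stratum == "within_1sd"], 2)
  expect_equal(sm$strata$n[sm$strata$stratum == "beyond_1sd"], 0)

  # a single reference in the day cannot define a daily SD -> unassigned
  ds1 <- make_dataset(sample_min = 0:500, sample_val = rep(100, 501),
                      ref_min = 100, ref_val = 100, removal_min = 501)
  p1 <- extract_pairs(ds1)
  sm1 <- mard_by_variability(p1, ds1)
  expect_equal(sm1$n_unassigned, 1)
})

test_that("pairs during excursions beyond 1 SD show the lag-inflated MARD", {
  # Dysglycemic excursions large against a quiet baseline put the beyond-1-SD
  # references on the steep episode flanks, where the first-order lag error
  # (slope x tau) is greatest; steady-state references near the daily mean
  # carry almost none of it.
  co <- simulate_cohort(sim_config(n_patients = 20, seed = 77, lag_min = 20,
                                   bg_sd = 12, episode_rate_per_day = 2,
                                   episode_amp_mean = 80,
                                   sensor_noise_sd = 1, drift_sd_per_hour = 0,
                                   pre_hours = 0, post_hours = 0))
  p <- extract_pairs(co$dataset)
  sm <- mard_by_variability(p, co$dataset)
  within <- sm$strata$mard_median[sm$strata$stratum == "within_1sd"]
  beyond <- sm$strata$mard_median[sm$strata$stratum == "beyond_1sd"]
  expect_gt(beyond, within)
  expect_lt(sm$test$p, 0.05)
})

test_that("covariate screening reports correlations and group tests", {
  co <- simulate_cohort(quick_config(seed = 41))
  p <- extract_pairs(co$dataset)
  cc <- suppressMessages(covariate_correlations(p, co$dataset))
  expect_true(all(c("pO2", "SOFA") %in% cc$covariate))
  expect_equal(unique(cc$type[cc$covariate == "pO2"]), "correlation")
  expect_true(all(cc$p >= 0 & cc$p <= 1))
  expect_equal(cc$r_squared[cc$type == "correlation"],
               cc$rho[cc$type == "correlation"]^2)

  # ARD constructed as a monotone function of a covariate -> rho ~ 1
  ds <- make_dataset(sample_min = 0:2000, sample_val = rep(100, 2001),
                     ref_min = seq(100, 1900, by = 100),
                     ref_val = 100 + seq_len(19), removal_min = 2001)
  ds$covariates <- data.frame(patient_id = "P01",
                              timestamp = min_at(seq(100, 1900, by = 100)),
                              name = "marker", value = seq_len(19))
  pp <- extract_pairs(ds)
  ccc <- covariate_correlations(pp, ds)
  expect_gt(ccc$rho[ccc$covariate == "marker"], 0.99)

  # no covariates at all -> empty result with a notice
  ds2 <- make_dataset(sample_min = 0:10, sample_val = rep(100, 11),
                      removal_min = 11)
  expect_message(out <- covariate_correlations(make_pairs(100, 90), ds2),
                 "no covariates")
  expect_equal(nrow(out), 0)
})

test_that("the lag profile at shift zero reproduces the unshifted MARD exactly", {
  co <- simulate_cohort(quick_config(seed = 51))
  p <- extract_pairs(co$dataset)
  lp <- time_shift_mard(co$dataset)
  expect_equal(lp$mard0, mard(p)$mard)
  expect_equal(lp$profile$n[lp$profile$shift == 0], nrow(p))
})

test_that("a constant glucose trajectory yields a flat lag profile", {
  ds <- make_dataset(sample_min = 0:1000, sample_val = rep(100, 1001),
                     ref_min = seq(100, 900, by = 200),
                     ref_val = rep(100, 5), removal_min = 1001)
  lp <- time_shift_mard(ds, shifts = 0:10)
  expect_equal(diff(range(lp$profile$mard)), 0)
})

test_that("shifts beyond the trace span are omitted", {
  ds <- make_dataset(sample_min = 0:20, sample_val = rep(100, 21),
                     ref_min = 18, ref_val = 100, removal_min = 21)
  lp <- time_shift_mard(ds, shifts = c(0, 2, 25))
  expect_equal(lp$profile$shift, c(0, 2))
})
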