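# Hand-built dataset: 2 patients, reference draws every 2 h for 9 days,
# CGM session in the middle 72 h. Patient P02 has hyperglycemic excursions
# only during the monitored period.
comparison_dataset <- function() {
  day <- 1440
  cgm_start <- 3 * day
  cgm_end <- 6 * day
  ref_min <- seq(0, 9 * day - 1, by = 120)
  mk_vals <- function(hyper_during) {
    vapply(ref_min, function(m) {
      base <- 120 + 10 * sin(2 * pi * m / 1440)  # daily cycle
      if (hyper_during && m >= cgm_start && m < cgm_end && (m %/% 120) %% 4 == 0)
        base + 70 else base
    }, 0)
  }
  sensor_min <- cgm_start:(cgm_end - 1)
  rows <- function(pid, hyper) {
    list(
      cgm = data.frame(patient_id = pid, sensor_id = paste0(pid, "S1"),
                       timestamp = min_at(sensor_min),
                       glucose_mgdl = 120 + 10 * sin(2 * pi * sensor_min / 1440)),
      ref = data.frame(patient_id = pid, timestamp = min_at(ref_min),
                       glucose_mgdl = mk_vals(hyper), source = "arterial"),
      ses = data.frame(patient_id = pid, sensor_id = paste0(pid, "S1"),
                       init_time = min_at(cgm_start),
                       removal_time = min_at(cgm_end), removal_cause = NA)
    )
  }
  a <- rows("P01", FALSE); b <- rows("P02", TRUE)
  cgm_dataset(cgm = rbind(a$cgm, b$cgm), reference = rbind(a$ref, b$ref),
              calibrations = data.frame(patient_id = character(0),
                                        sensor_id = character(0),
                                        timestamp = min_at(numeric(0)),
                                        reference_mgdl = numeric(0)),
              sessions = rbind(a$ses, b$ses))
}

test_that("longitudinal windows anchor on the monitored span and compare metrics", {
  ds <- comparison_dataset()
  lc <- longitudinal_compare(ds)
  expect_s3_class(lc, "cgm_longitudinal")
  expect_equal(sort(unique(as.character(lc$per_patient$window))),
               sort(c("before", "during", "after")))
  p2 <- lc$per_patient[lc$per_patient$patient_id == "P02", ]
  expect_gt(p2$events_hyper[p2$window == "during"],
            p2$events_hyper[p2$window == "before"])
  expect_equal(p2$events_hyper[p2$window == "before"], 0)
  # the untouched patient repeats the same daily cycle in all windows
  p1 <- lc$per_patient[lc$per_patient$patient_id == "P01", ]
  expect_lt(max(p1$mean) - min(p1$mean), 0.01)
})

test_that("patients without full before/after coverage are excluded and logged", {
  ds <- comparison_dataset()
  # drop P02's pre-CGM references
  keep <- !(ds$reference$patient_id == "P02" &
            mins_of(ds$reference$timestamp) < 3 * 1440)
  ds$reference <- ds$reference[keep, ]
  lc <- longitudinal_compare(ds)
  expect_equal(lc$excluded, "P02")
  expect_equal(unique(lc$per_patient$patient_id), "P01")
})

test_that("parallel comparison of a sensor equal to the reference path gives zero differences", {
  day <- 1440
  sensor_min <- 0:(3 * day - 1)
  vals <- 120 + 15 * sin(sensor_min / 400)
  ref_idx <- seq(1, length(sensor_min), by = 120)
  ds <- cgm_dataset(
    cgm = data.frame(patient_id = "P01", sensor_id = "P01S1",
                     timestamp = min_at(sensor_min), glucose_mgdl = vals),
    reference = data.frame(patient_id = "P01",
                           timestamp = min_at(sensor_min[ref_idx]),
                           glucose_mgdl = vals[ref_idx], source = "arterial"),
    calibrations = data.frame(patient_id = character(0), sensor_id = character(0),
                              timestamp = min_at(numeric(0)),
                              reference_mgdl = numeric(0)),
    sessions = data.frame(patient_id = "P01", sensor_id = "P01S1",
                          init_time = min_at(0), removal_time = min_at(3 * day),
                          removal_cause = NA))
  pc <- parallel_compare(ds, extract_pairs(ds))
  expect_equal(pc$patients, "P01")
  per <- pc$per_patient
  expect_equal(per$mean[per$series == "intermittent"],
               per$mean[per$series == "cgm"], tolerance = 0.5)
  # identical sampled values -> identical extremes of the sampled subsets? no:
  # the dense series has more readings and at least as extreme a range
  expect_lte(per$min[per$series == "cgm"], per$min[per$series == "intermittent"])
  expect_gte(per$max[per$series == "cgm"], per$max[per$series == "intermittent"])
  expect_gt(per$n_readings[per$series == "cgm"],
            per$n_readings[per$series == "intermittent"])
})

test_that("the accuracy filter never widens the parallel cohort when tightened", {
  co <- simulate_cohort(quick_config(seed = 61))
  p <- extract_pairs(co$dataset)
  all_in <- parallel_compare(co$dataset, p, mard_threshold = Inf)
  tight <- parallel_compare(co$dataset, p, mard_threshold = 14)
  tighter <- parallel_compare(co$dataset, p, mard_threshold = 5)
  expect_equal(length(all_in$patients), length(unique(p$patient_id)))
  expect_lte(length(tight$patients), length(all_in$patients))
  expect_lte(length(tighter$patients), length(tight$patients))
})

test_that("dense continuous sampling catches nadirs the intermittent series misses", {
  co <- simulate_cohort(quick_config(seed = 71))
  pc <- parallel_compare(co$dataset, extract_pairs(co$dataset),
                         mard_threshold = Inf)
  per <- pc$per_patient
  mins_cgm <- per$min[per$series == "cgm"]
  mins_int <- per$min[per$series == "intermittent"]
  expect_true(all(mins_cgm <= mins_int + 1e-9))
})

test_that("no qualifying patient yields an empty parallel report, not an error", {
  co <- simulate_cohort(quick_config(seed = 81))
  pc <- parallel_compare(co$dataset, extract_pairs(co$dataset),
                         mard_threshold = 0)
  expect_s3_class(pc, "cgm_parallel")
  expect_length(pc$patients, 0)
  expect_output(print(pc), "0 patients")
})
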