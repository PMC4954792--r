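# One 12-h session with a 20-min display gap (minutes 240-259) and the
# standard calibration schedule; display resumes at minute 260 where a
# fresh calibration is entered.
gap_session_dataset <- function() {
  shown <- setdiff(0:719, 240:259)
  make_dataset(sample_min = shown, sample_val = rep(110, length(shown)),
               cal_min = c(0, 60, 120, 260, 600),
               cal_val = rep(110, 5), removal_min = 720)
}

test_that("calibrations classify as initial, post-gap or scheduled", {
  ds <- gap_session_dataset()
  ses <- sensor_sessions(ds)[[1]]
  kinds <- classify_calibrations(ses)$kind
  expect_equal(kinds, c("initial", "initial", "initial", "post_gap", "scheduled"))
  expect_equal(classify_calibration(ses, min_at(0)), "initial")
  expect_equal(classify_calibration(ses, min_at(260)), "post_gap")
  expect_equal(classify_calibration(ses, min_at(600)), "scheduled")
  expect_error(classify_calibration(ses, min_at(50)), "no calibration event")
})

test_that("a calibration outside the session span is an error", {
  ds <- make_dataset(sample_min = 0:100, sample_val = rep(100, 101),
                     cal_min = 150, cal_val = 100, removal_min = 101)
  expect_error(classify_calibrations(sensor_sessions(ds)[[1]]),
               "outside session span")
})

test_that("pairs use the latest sensor value at or before the reference", {
  ds <- make_dataset(sample_min = c(0, 5, 9), sample_val = c(80, 85, 90),
                     ref_min = 10, ref_val = 100, removal_min = 60)
  p <- extract_pairs(ds)
  expect_equal(nrow(p), 1)
  expect_equal(p$sensor_mgdl, 85 + 5)  # minute 9 value, 1 min stale
  expect_equal(p$ard_pct, 10)
  expect_equal(p$sensor_age_min, 1)

  # same-minute tie: the same-minute sensor value is used
  ds2 <- make_dataset(sample_min = c(0, 10), sample_val = c(80, 85),
                      ref_min = 10, ref_val = 100, removal_min = 60)
  p2 <- extract_pairs(ds2)
  expect_equal(p2$sensor_mgdl, 85)
  expect_equal(p2$ard_pct, 15)
  expect_equal(p2$sensor_age_min, 0)
})

test_that("initial/post-gap calibration references are excluded, scheduled kept", {
  ds <- gap_session_dataset()
  # make every calibration minute also a reference draw, plus one routine draw
  ds2 <- make_dataset(sample_min = setdiff(0:719, 240:259),
                      sample_val = rep(110, 700),
                      ref_min = c(0, 60, 120, 260, 600, 400),
                      ref_val = rep(110, 6),
                      cal_min = c(0, 60, 120, 260, 600),
                      cal_val = rep(110, 5), removal_min = 720)
  p <- extract_pairs(ds2)
  counts <- attr(p, "counts")
  expect_equal(unname(counts["excluded_calibration"]), 4L)  # 3 initial + 1 post-gap
  expect_equal(sort(mins_of(p$timestamp)), c(400, 600))
  expect_true(p$is_calibration[p$timestamp == min_at(600)])
  expect_false(p$is_calibration[p$timestamp == min_at(400)])
  # scheduled calibrations can be filtered out on request
  p2 <- extract_pairs(ds2, include_scheduled_calibrations = FALSE)
  expect_equal(sort(mins_of(p2$timestamp)), 400)
})

test_that("references inside display gaps are unpairable, outside sessions ignored", {
  shown <- setdiff(0:719, 200:259)  # 60-min gap
  ds <- make_dataset(sample_min = shown, sample_val = rep(110, length(shown)),
                     ref_min = c(230, 900), ref_val = c(100, 100),
                     removal_min = 720)
  p <- extract_pairs(ds)
  counts <- attr(p, "counts")
  expect_equal(nrow(p), 0)
  expect_equal(unname(counts["unpairable"]), 1L)
  expect_equal(unname(counts["out_of_session"]), 1L)
})

test_that("with no gaps and scheduled-only calibrations every non-initial reference pairs", {
  co <- simulate_cohort(quick_config(seed = 21, gap_rate_per_hour = 0,
                                     pre_hours = 0, post_hours = 0))
  p <- extract_pairs(co$dataset)
  counts <- attr(p, "counts")
  expect_equal(unname(counts["unpairable"]), 0L)
  # only the three initial calibrations per sensor are excluded
  expect_equal(unname(counts["excluded_calibration"]),
               3L * nrow(co$dataset$sessions))
})

test_that("ARD is scale invariant", {
  p1 <- make_pairs(c(100, 150, 80), c(90, 160, 75))
  p2 <- make_pairs(c(100, 150, 80) * 3.7, c(90, 160, 75) * 3.7)
  expect_equal(p1$ard_pct, p2$ard_pct)
})

test_that("the inclusion rule admits by monitoring time or by pair count", {
  mk <- function(hours, npairs) {
    ref_min <- if (npairs) seq(10, by = 10, length.out = npairs) else numeric(0)
    make_dataset(sample_min = 0:(hours * 60 - 1), sample_val = rep(100, hours * 60),
                 ref_min = ref_min, ref_val = rep(100, npairs),
                 removal_min = hours * 60)
  }
  ds <- mk(50, 8)
  d <- apply_inclusion(ds, extract_pairs(ds))
  expect_true(d$included)
  expect_match(d$reason, "48")

  ds <- mk(24, 12)
  d <- apply_inclusion(ds, extract_pairs(ds))
  expect_true(d$included)
  expect_match(d$reason, "12")

  ds <- mk(24, 5)
  d <- apply_inclusion(ds, extract_pairs(ds))
  expect_false(d$included)
})
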