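test_that("gap detection finds interruptions of the display, not early removal", {
  s <- make_session(sample_min = c(0:9, 20:30), sample_val = rep(100, 21),
                    removal_min = 31)
  g <- detect_gaps(s)
  expect_equal(nrow(g), 1)
  expect_equal(g$duration_min, 10)
  expect_equal(mins_of(g$start), 10)
  expect_equal(mins_of(g$end), 19)

  full <- make_session(sample_min = 0:(72 * 60 - 1), sample_val = rep(100, 4320),
                       removal_min = 4320)
  expect_equal(nrow(detect_gaps(full)), 0)

  # removal before 72 h leaves no trailing gap record
  early <- make_session(sample_min = 0:999, sample_val = rep(100, 1000),
                        removal_min = 1000)
  expect_equal(nrow(detect_gaps(early)), 0)
})

test_that("injected gaps of known durations are recovered exactly", {
  gaps <- list(c(100, 5), c(300, 20), c(600, 60), c(1000, 130))
  missing <- unlist(lapply(gaps, function(g) g[1]:(g[1] + g[2] - 1)))
  shown <- setdiff(0:2999, missing)
  s <- make_session(sample_min = shown, sample_val = rep(100, length(shown)),
                    removal_min = 3000)
  g <- detect_gaps(s)
  expect_equal(g$duration_min, c(5, 20, 60, 130))
  expect_equal(g$category, c("very_brief", "brief", "prolonged", "very_prolonged"))
})

test_that("generator-injected gaps round-trip through detection", {
  co <- simulate_cohort(quick_config(seed = 17, gap_rate_per_hour = 0.4))
  ses <- sensor_sessions(co$dataset)
  for (pid in names(co$truth)) {
    for (sid in names(co$truth[[pid]]$sessions)) {
      truth_gaps <- co$truth[[pid]]$sessions[[sid]]$gaps
      got <- detect_gaps(ses[[sid]])
      expect_equal(got$duration_min, truth_gaps$duration)
      expect_equal(got$cause_code, truth_gaps$cause)
    }
  }
})

test_that("gap categories split at 15, 30 and 120 minutes", {
  expect_equal(classify_gap(c(1, 10, 14)), rep("very_brief", 3))
  expect_equal(classify_gap(c(15, 22, 30)), rep("brief", 3))
  expect_equal(classify_gap(c(31, 120)), rep("prolonged", 2))
  expect_equal(classify_gap(c(121, 500)), rep("very_prolonged", 2))
  expect_error(classify_gap(0))
})

test_that("per-sensor display percentages use both denominators", {
  # 32.5 h displayed, removed at 37.9 h (of an expected 72 h)
  shown_min <- round(32.5 * 60)
  actual_min <- round(37.9 * 60)
  s <- make_session(sample_min = c(0:(shown_min - 2), actual_min - 1),
                    sample_val = rep(100, shown_min),
                    removal_min = actual_min)
  rep_ <- reliability_summary(list(s))
  per <- rep_$per_sensor
  expect_equal(round(per$pct_display_of_expected, 1), 45.1)
  expect_equal(per$displayed_min + per$gap_min, per$actual_min)
  expect_gte(per$pct_display_of_actual, per$pct_display_of_expected)

  full <- make_session(sample_min = 0:(4320 - 1), sample_val = rep(100, 4320),
                       removal_min = 4320)
  rep2 <- reliability_summary(list(full))
  expect_equal(rep2$per_sensor$pct_display_of_expected, 100)
  expect_equal(rep2$per_sensor$pct_display_of_actual, 100)
  expect_true(rep2$consensus$pass)
})

test_that("cause shares split gap minutes by annotated cause", {
  shown <- setdiff(0:999, c(100:199, 500:599))  # two 100-min gaps
  gc <- data.frame(patient_id = "P01", sensor_id = "P01S1",
                   start_time = min_at(c(100, 500)), cause_code = c(1, 4))
  ds <- make_dataset(sample_min = shown, sample_val = rep(100, length(shown)),
                     removal_min = 1000, gap_causes = gc)
  rep_ <- reliability_summary(ds)
  shares <- rep_$cohort$cause_share_of_gap_min
  expect_equal(unname(shares["1"]), 50)
  expect_equal(unname(shares["4"]), 50)
  expect_equal(sum(shares), 100)
  # a 100-min device-related gap violates the consensus gap criterion
  expect_false(rep_$consensus$gaps_ok)
})

test_that("cohort bookkeeping is consistent on a simulated cohort", {
  co <- simulate_cohort(quick_config(seed = 29))
  rel <- reliability_summary(co$dataset)
  expect_equal(sum(rel$cohort$gap_counts), rel$cohort$n_gaps)
  expect_equal(rel$per_sensor$displayed_min + rel$per_sensor$gap_min,
               rel$per_sensor$actual_min)
  expect_true(all(rel$per_sensor$pct_display_of_actual >=
                  rel$per_sensor$pct_display_of_expected - 1e-9))
  expect_equal(sum(rel$cohort$cause_share_of_gap_min), 100, tolerance = 1e-6)
  expect_equal(nrow(rel$gaps), rel$cohort$n_gaps)

  nogap <- simulate_cohort(quick_config(seed = 29, gap_rate_per_hour = 0))
  rel0 <- reliability_summary(nogap$dataset)
  expect_true(all(rel0$per_sensor$pct_display_of_actual == 100))
})
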