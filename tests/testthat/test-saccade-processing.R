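test_that("a clean step-like saccade is detected with the right onset, amplitude and direction", {
  tr <- make_ramp_trace(200, 10, "right")
  ev <- detect_first_saccade(tr)
  expect_false(is.null(ev))
  expect_equal(ev$direction, "right")
  expect_lt(abs(ev$onset_ms - 200), 1000 / 240)
  expect_lt(abs(ev$amplitude_deg - 10), 0.3)

  # an instantaneous step is also recovered to within one sample
  t <- seq(0, 800, by = 1000 / 240)
  x <- ifelse(t >= 400, 10, 0)    # cue at 200, step at cue+200
  ev2 <- detect_first_saccade(gaze_trace(t, x, 200))
  expect_false(is.null(ev2))
  expect_lt(abs(ev2$onset_ms - 200), 1.5 * 1000 / 240)
})

test_that("flat traces and sub-amplitude movements yield no saccade", {
  set.seed(5)
  t <- seq(0, 800, by = 1000 / 240)
  flat <- gaze_trace(t, rnorm(length(t), 0, 0.1), 200)
  expect_null(detect_first_saccade(flat))
  small <- make_ramp_trace(200, 1.5, "right")   # below the 2 degree criterion
  expect_null(detect_first_saccade(small))
  # exactly at the criterion is still excluded ("larger than")
  at <- make_ramp_trace(200, 2, "right")
  expect_null(detect_first_saccade(at))
})

test_that("malformed traces are rejected", {
  expect_error(gaze_trace(c(0, 10, 5), c(0, 0, 0), 1), "strictly increasing")
  expect_error(gaze_trace(c(0, 10), c(0, 0), 50), "within the trace span")
  expect_error(gaze_trace(0, 0, 0), "at least 2 samples")
})

test_that("detection is invariant under time/position translation and mirrors correctly", {
  base <- make_ramp_trace(180, 6, "right")
  ev <- detect_first_saccade(base)
  shifted <- gaze_trace(base$t_ms + 130, base$x_deg + 4,
                        attr(base, "cue_onset_ms") + 130)
  ev_s <- detect_first_saccade(shifted)
  expect_equal(ev_s$onset_ms, ev$onset_ms, tolerance = 1e-6)
  expect_equal(ev_s$amplitude_deg, ev$amplitude_deg, tolerance = 1e-6)
  expect_equal(ev_s$direction, ev$direction)

  mirrored <- gaze_trace(base$t_ms, -base$x_deg, attr(base, "cue_onset_ms"))
  ev_m <- detect_first_saccade(mirrored)
  expect_equal(ev_m$direction, "left")
  expect_equal(ev_m$onset_ms, ev$onset_ms, tolerance = 1e-6)
  expect_equal(ev_m$amplitude_deg, ev$amplitude_deg, tolerance = 1e-6)
})

test_that("only the first suprathreshold saccade is scored", {
  # main saccade at cue+150 followed by a corrective saccade at cue+400
  t <- seq(0, 900, by = 1000 / 240)
  x <- 8 * pmin(1, pmax(0, (t - 350) / 40)) - 3 * pmin(1, pmax(0, (t - 600) / 30))
  ev <- detect_first_saccade(gaze_trace(t, x, 200))
  expect_lt(abs(ev$onset_ms - 150), 1000 / 240)
  expect_equal(ev$direction, "right")
})

test_that("trial scoring applies the latency filters with inclusive bounds", {
  ev <- function(rt) structure(list(onset_ms = rt, amplitude_deg = 8,
                                    direction = "right"),
                               class = "saccade_event")
  expect_equal(score_trial(ev(90), "right", "congruent")$status,
               "rejected_anticipation")
  expect_equal(score_trial(ev(510), "right", "congruent")$status,
               "rejected_delay")
  r <- score_trial(ev(250), "right", "congruent")
  expect_equal(r$status, "kept"); expect_true(r$correct)
  expect_equal(score_trial(ev(100), "right", "congruent")$status, "kept")
  expect_equal(score_trial(ev(500), "right", "congruent")$status, "kept")
  expect_equal(score_trial(NULL, "left", "incongruent")$status,
               "excluded_no_saccade")
  w <- score_trial(ev(250), "left", "incongruent")
  expect_false(w$correct)
})

test_that("filter summary reproduces the design-level exclusion percentages", {
  n <- 5376
  status <- rep(c("excluded_no_saccade", "rejected_anticipation",
                  "rejected_delay", "kept"),
                c(725, 90, 91, n - 725 - 181))
  fs <- filter_summary(data.frame(status = status))
  expect_equal(fs$n_total, n)
  expect_equal(round(fs$pct_no_saccade, 1), 13.5)
  expect_equal(fs$pct_rejected_of_total, 100 * 181 / 5376, tolerance = 1e-10)
  expect_equal(fs$pct_rejected_of_detected, 100 * 181 / 4651, tolerance = 1e-10)
  expect_equal(sum(fs$table$n), n)                  # exhaustive partition
  expect_equal(sum(fs$table$pct_total), 100, tolerance = 1e-9)

  all_kept <- filter_summary(data.frame(status = rep("kept", 10)))
  expect_equal(all_kept$pct_no_saccade, 0)
  expect_equal(all_kept$pct_rejected_of_total, 0)
})
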