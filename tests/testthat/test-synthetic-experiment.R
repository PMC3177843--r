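test_that("the same seed reproduces the dataset bit for bit", {
  a <- generate_cohort(cohort_config(seed = 1))
  b <- generate_cohort(cohort_config(seed = 1))
  expect_identical(a$trials, b$trials)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$character_ratings, b$character_ratings)
  c2 <- generate_cohort(cohort_config(seed = 2))
  expect_false(identical(a$trials, c2$trials))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(cohort_config(p_no_saccade = 1.4), "p_no_saccade")
  expect_error(cohort_config(n_per_group = c(left = 0L)), "n_per_group")
  expect_error(cohort_config(reps_per_cell = 0), "reps_per_cell")
  bad <- array(0.7, dim = c(2, 4, 2),
               dimnames = list(c("left", "right"),
                               c("a", "b", "c", "d"),
                               c("congruent", "incongruent")))
  expect_error(cohort_config(err_prob = bad, characters = c("a", "b", "c", "d")),
               "err_prob")
  expect_error(cohort_config(similarity_coupling = 1.5), "similarity_coupling")
})

test_that("the design is balanced before stochastic exclusions", {
  co <- generate_cohort(cohort_config(seed = 3))
  tr <- co$trials
  expect_equal(nrow(tr), 28 * 4 * 48)
  per_block <- table(tr$participant_id, tr$character)
  expect_true(all(per_block == 48))
  cells <- table(tr$congruency, tr$cue_direction, tr$character, tr$participant_id)
  expect_true(all(cells == 12))
})

test_that("a noise-free error-free cohort shows zero interference everywhere", {
  zero <- array(0, dim = c(2, 4, 2),
                dimnames = list(c("left", "right"),
                                c("DiPietro", "Prodi", "Berlusconi", "Vespa"),
                                c("congruent", "incongruent")))
  cfg <- cohort_config(err_prob = zero, p_no_saccade = 0, p_anticipation = 0,
                       p_delay = 0, subject_sd = 0, cell_sd = 0, seed = 4)
  co <- generate_cohort(cfg)
  sc <- score_trials(co$trials)
  expect_true(all(sc$status == "kept"))
  expect_true(all(sc$correct))
  it <- interference_table(sc)
  expect_true(all(it$acc_interference == 0))
})

test_that("per-cell error rates match the configured probabilities (binomial check)", {
  # one participant, two characters, 5000 reps -> 10,000 trials per congruency
  chars <- c("target", "other")
  ep <- array(0.05, dim = c(1, 2, 2),
              dimnames = list("g1", chars, c("congruent", "incongruent")))
  ep["g1", "target", "incongruent"] <- 0.25
  cfg <- cohort_config(n_per_group = c(g1 = 1L), characters = chars,
                       reps_per_cell = 2500L, err_prob = ep,
                       p_no_saccade = 0, p_anticipation = 0, p_delay = 0,
                       subject_sd = 0, cell_sd = 0, seed = 5)
  co <- generate_cohort(cfg)
  sc <- score_trials(co$trials)
  tgt <- sc[sc$character == "target", ]
  # binomial SE of the interference estimate is ~0.5 points here
  expect_equal(interference_accuracy(tgt), 20, tolerance = 2 / 20)
  err_cong <- 1 - mean(tgt$correct[tgt$congruency == "congruent"])
  expect_equal(err_cong, 0.05, tolerance = 0.01 / 0.05)
})

test_that("empirical exclusion fraction converges to the configured loss probabilities", {
  cfg <- cohort_config(n_per_group = c(g1 = 2L), characters = c("a", "b"),
                       reps_per_cell = 500L,
                       acc_targets = rbind(g1 = c(5, 5)), seed = 6)
  co <- generate_cohort(cfg)
  sc <- score_trials(co$trials)
  frac <- mean(sc$status != "kept")
  expect_equal(frac, 0.135 + 0.017 + 0.017, tolerance = 0.1)
})

test_that("RT structure: congruency cost near the configured shift", {
  cfg <- cohort_config(n_per_group = c(g1 = 4L), characters = c("a", "b"),
                       reps_per_cell = 400L, acc_targets = rbind(g1 = c(0, 0)),
                       subject_sd = 0, cell_sd = 0, seed = 7)
  co <- generate_cohort(cfg)
  sc <- score_trials(co$trials)
  rt_int <- interference_rt(sc)
  expect_equal(rt_int, 33, tolerance = 5 / 33)
  expect_true(all(sc$rt_ms[sc$status == "kept"] >= 100 &
                  sc$rt_ms[sc$status == "kept"] <= 500))
})

test_that("perceived similarity correlates with injected interference at the coupling", {
  for (s in 1:3) {
    co <- generate_cohort(cohort_config(similarity_coupling = 0.5, seed = 100 + s))
    st <- similarity_table(co$ratings, co$character_ratings)
    m <- merge(st, co$injected, by = c("participant_id", "character"))
    expect_equal(cor(m$perceived, m$injected_interference), 0.5, tolerance = 0.3)
  }
})

test_that("with zero coupling the estimated similarity-interference correlation is centered on 0", {
  rs <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(similarity_coupling = 0, seed = 8000 + s))
    it <- interference_table(score_trials(co$trials))
    st <- similarity_table(co$ratings, co$character_ratings)
    m <- merge(it, st, by = c("participant_id", "character"))
    cor(m$perceived, m$acc_interference, use = "complete.obs")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.08)
})

test_that("trace generator round-trips through the detector (direction exact, RT within a sample)", {
  set.seed(11)
  period <- 1000 / 240
  # at the generator's default noise the recovery is strict for every case
  for (amp in c(3, 5, 8, 12)) {
    rt <- runif(1, 120, 420)
    dir <- sample(c("left", "right"), 1)
    ev <- detect_first_saccade(generate_trace(rt, amp, dir))
    expect_false(is.null(ev))
    expect_equal(ev$direction, dir)
    expect_lte(abs(ev$onset_ms - rt), period)
    expect_equal(ev$amplitude_deg, amp, tolerance = 0.5 / 3)
  }
  # up to 0.3 deg position noise the onset estimate is a noisy statistic:
  # direction stays exact and the one-sample bound holds in the vast
  # majority of trials, with no gross (> 2.5 sample) misses
  errs <- replicate(24, {
    rt <- runif(1, 120, 420)
    amp <- runif(1, 3, 12)
    dir <- sample(c("left", "right"), 1)
    ns <- sample(c(0.2, 0.3), 1)
    ev <- detect_first_saccade(generate_trace(rt, amp, dir, noise_sd = ns))
    expect_equal(ev$direction, dir)
    abs(ev$onset_ms - rt)
  })
  expect_gte(mean(errs <= period), 0.9)
  expect_lte(max(errs), 2.5 * period)
  # amplitude zero: no saccade; direction sign convention
  expect_null(detect_first_saccade(generate_trace(200, 0, "right")))
  trl <- generate_trace(200, 8, "left", noise_sd = 0.05)
  expect_lt(trl$x_deg[length(trl$x_deg)], -5)
})

test_that("generator errors on invalid trace requests", {
  expect_error(generate_trace(200, 8, "right", sampling_hz = 0), "sampling_hz")
  expect_error(generate_trace(200, -1, "right"), "nonnegative")
  expect_error(generate_trace(2000, 8, "right", duration_ms = 800), "outside")
})

test_that("written dataset round-trips as CSV with provenance", {
  co <- generate_cohort(cohort_config(n_per_group = c(left = 2L, right = 2L),
                                      seed = 12))
  dir <- tempfile("cohort")
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  tr <- read.csv(file.path(dir, "trials.csv"))
  expect_equal(nrow(tr), nrow(co$trials))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 12)
})
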