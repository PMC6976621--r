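test_that("estimate_sigma is the trailing-window sample SD", {
  x <- rep(c(27, 29), 20)
  expect_equal(estimate_sigma(x), sd_two_pass(x))
  # only the last 40 trials count
  expect_equal(estimate_sigma(c(runif(10, 0, 100), x)), estimate_sigma(x))
  expect_error(estimate_sigma(rnorm(39)), "insufficient")
  # zero-variance history is legal here but rejected downstream
  expect_equal(estimate_sigma(rep(28, 40)), 0)
  expect_error(run_competitive_block(28, 1, 1, rep(28, 40)), "degenerate")
})

test_that("opponent endpoints follow N(alpha * E*, sigma^2)", {
  set.seed(11)
  draws <- sample_opponent_endpoint(0.925, 28.0, 1.0, n = 1e5)
  expect_equal(mean(draws), 0.925 * 28.0, tolerance = 4 / sqrt(1e5))
  expect_equal(sd(draws), 1.0, tolerance = 0.02)
  set.seed(22)
  a <- sample_opponent_endpoint(1, 27, 1.2, n = 10)
  set.seed(22)
  b <- sample_opponent_endpoint(1, 27, 1.2, n = 10)
  expect_identical(a, b)
  expect_error(sample_opponent_endpoint(1, 27, 0), "positive")
})

test_that("subject aim rule composes bias, two-slope response and inhibition", {
  m <- subject_model(baseline_bias = 0.9, inhibition = 0,
                     slope_pos = 0.63, slope_neg = 0.21)
  # null response: baseline aim
  expect_equal(subject_block_aim(m, 27, opp_relative_aim = 0), 27.9)
  # opponent below the baseline engages the shallow slope
  expect_equal(subject_block_aim(m, 27, opp_relative_aim = -2),
               27.9 - 0.42)
  # opponent above engages the steep slope
  expect_equal(subject_block_aim(m, 27, opp_relative_aim = 0.5),
               27.9 + 0.315)
  # inhibition: full at trial 1 of block 1, gone by trial 6 and in block 2
  mi <- subject_model(baseline_bias = 0.9, inhibition = 1,
                      inhibition_decay_trials = 5)
  base <- subject_block_aim(mi, 27, 0, block_index = 2, trial_index = 1)
  expect_equal(subject_block_aim(mi, 27, 0, 1, 1), base - 1)
  expect_equal(subject_block_aim(mi, 27, 0, 1, 3), base - 0.6)
  expect_equal(subject_block_aim(mi, 27, 0, 1, 6), base)
  # jitter enters additively
  expect_equal(subject_block_aim(m, 27, NULL, jitter = 0.2), 28.1)
})

test_that("opponent schedules expose the study presets", {
  s1a <- opponent_schedule("exp1a")
  expect_equal(s1a$alpha, rep(1, 12))
  s1b <- opponent_schedule("exp1b")
  expect_equal(s1b$alpha,
               c(1, 1, 1, 1, 0.985, 0.970, 0.955, 0.940, rep(0.925, 4)))
  expect_equal(opponent_schedule("exp1c")$alpha, rep(1, 4))
  s4 <- opponent_schedule("exp4")
  expect_equal(s4$alpha, rep(0.925, 12))
  expect_equal(s4$sigma_mode, "frozen_baseline")
  expect_error(opponent_schedule("exp99"), "unknown")
  expect_error(opponent_schedule(alpha = c(1, -0.5)), "positive")
})

test_that("cohorts are structured, reproducible and extendable", {
  m <- subject_model()
  trials <- generate_cohort("exp1b", 2, m, seed = 7)
  # 5 baseline + 12 competitive + 5 washout blocks of 10 trials per subject
  counts <- dplyr::count(trials, subject_id, session, role)
  expect_equal(sort(unique(counts$n)), c(50, 120))
  one <- dplyr::filter(trials, subject_id == "s01")
  expect_equal(sum(one$session == "baseline"), 50)
  expect_equal(sum(one$session == "competition" & one$role == "subject"), 120)
  expect_equal(sum(one$session == "competition" & one$role == "opponent"), 120)
  expect_equal(sum(one$session == "washout"), 50)
  # byte-identical under the same seed
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(trials, f1)
  write_trial_table(generate_cohort("exp1b", 2, m, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
  # adding subjects never perturbs earlier ones
  bigger <- generate_cohort("exp1b", 3, m, seed = 7)
  expect_identical(dplyr::filter(bigger, subject_id != "s03"), trials)
  # empty cohort: valid header, no rows
  empty <- generate_cohort("exp1b", 0, m, seed = 7)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("subject_id", "session", "endpoint_cm", "score") %in%
                    names(empty)))
  expect_error(generate_cohort("nope", 2, m, seed = 1), "unknown")
})
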