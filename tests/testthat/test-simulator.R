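test_that("individual blocks score each reach by the gain function", {
  gf <- gain_function()
  blk <- run_individual_block(29, sigma = 0, gf)
  expect_equal(blk$score, rep(gain(29, gf), 10))
  expect_equal(nrow(blk), 10)
  # additivity of the block total
  set.seed(5)
  blk2 <- run_individual_block(28, sigma = 1.5, gf)
  expect_identical(blk2$score, gain(blk2$endpoint_cm, gf))
  expect_equal(sum(blk2$score),
               summarize_blocks(blk2)$subject_total)
  set.seed(9); a <- run_individual_block(28, 1, gf)
  set.seed(9); b <- run_individual_block(28, 1, gf)
  expect_identical(a, b)
})

test_that("competitive blocks alternate roles and track the block winner", {
  set.seed(31)
  hist40 <- rnorm(60, 28, 1.5)
  res <- run_competitive_block(28, 1.5, alpha = 0.925, history = hist40)
  expect_equal(res$trials$role, rep(c("subject", "opponent"), 10))
  expect_equal(res$summary$subject_total,
               sum(res$trials$score[res$trials$role == "subject"]))
  expect_true(res$summary$winner %in% c("subject", "opponent", "tie"))
  expect_error(run_competitive_block(28, 1.5, 1, history = rnorm(30)),
               "insufficient")
  # zeroing the subject's scores hands the block to the opponent
  zeroed <- dplyr::mutate(
    res$trials, score = ifelse(role == "subject", 0, score))
  expect_equal(summarize_blocks(zeroed)$winner, "opponent")
})

test_that("opponent block endpoints centre on alpha * E* in the long run", {
  set.seed(77)
  hist40 <- rnorm(40, 28, 1.5)
  sigma_hat <- estimate_sigma(hist40)
  e_star <- optimal_aim(sigma_hat)
  means <- replicate(300, {
    res <- run_competitive_block(28, 1.5, 0.925, hist40)
    res$summary$A_o
  })
  expect_equal(mean(means), 0.925 * e_star,
               tolerance = 4 * sigma_hat / sqrt(300 * 10))
})

test_that("matched players win about half their blocks", {
  set.seed(13)
  hist40 <- rnorm(40, 28, 1.5)
  sigma_hat <- estimate_sigma(hist40)
  e_star <- optimal_aim(sigma_hat)
  wins <- replicate(400, {
    res <- run_competitive_block(e_star, sigma_hat, 1, hist40)
    switch(res$summary$winner, subject = 1, opponent = 0, tie = 0.5)
  })
  expect_equal(mean(wins), 0.5, tolerance = 4 * sqrt(0.25 / 400))
})

test_that("protocol presets produce the study block structure", {
  p1a <- protocol("exp1a")
  expect_equal(sum(p1a$sessions$n_blocks), 22)
  expect_equal(p1a$sessions$n_blocks[p1a$sessions$session == "competition"],
               12)
  expect_equal(protocol("exp1c")$sessions$n_blocks, c(5, 17, 4))
  expect_equal(protocol("exp5_observation")$sessions$n_blocks, c(5, 12, 5))
  expect_error(protocol(sessions = data.frame(session = "warmup",
                                              n_blocks = 2)),
               "unknown session")
  expect_error(protocol("exp1a", schedule = opponent_schedule(alpha = 1)),
               "must match")
})

test_that("experiment runs respect protocol structure and conservation", {
  run <- run_experiment("exp1a", 2, subject_model(), seed = 3)
  blocks_per_subject <- dplyr::count(run$blocks, subject_id)
  expect_equal(blocks_per_subject$n, c(22, 22))
  expect_equal(sum(run$blocks$session == "competition"), 24)
  # conservation: block totals equal the sum of their trial scores, exactly
  recomputed <- summarize_blocks(run$trials)
  joined <- dplyr::inner_join(
    run$blocks, recomputed,
    by = c("subject_id", "group", "session", "block"))
  expect_identical(joined$subject_total.x, joined$subject_total.y)
  comp <- dplyr::filter(joined, session == "competition")
  expect_identical(comp$opponent_total.x, comp$opponent_total.y)
  expect_identical(comp$winner.x, comp$winner.y)
  # strict alternation in every competitive block
  alt <- run$trials |>
    dplyr::filter(session == "competition") |>
    dplyr::group_by(subject_id, block) |>
    dplyr::summarise(ok = all(role == rep(c("subject", "opponent"), 10)),
                     .groups = "drop")
  expect_true(all(alt$ok))
  # empty cohort
  empty <- run_experiment("exp1a", 0, seed = 1)
  expect_equal(nrow(empty$trials), 0)
  expect_equal(nrow(empty$blocks), 0)
})

test_that("exp2 emits an opponent-only presentation before competition", {
  run <- run_experiment("exp2", 1, subject_model(), seed = 21)
  pres <- dplyr::filter(run$trials, session == "presentation")
  expect_equal(nrow(pres), 10)
  expect_true(all(pres$role == "opponent"))
  sess <- unique(run$trials$session)
  expect_lt(which(sess == "presentation"), which(sess == "competition"))
})

test_that("exp4 freezes the opponent sigma at the baseline estimate", {
  run <- run_experiment("exp4", 1, subject_model(), seed = 15)
  comp <- dplyr::filter(run$blocks, session == "competition")
  expect_equal(length(unique(comp$sigma_hat)), 1)
  base <- dplyr::filter(run$trials, session == "baseline", role == "subject")
  expect_equal(unique(comp$sigma_hat),
               sd_two_pass(utils::tail(base$endpoint_cm, 40)))
  expect_true(all(comp$alpha == 0.925))
})

test_that("threshold totals equal the opponent's expected block score", {
  gf <- gain_function()
  # no-noise limit: ten perfect reaches at the (near-boundary) optimum
  expect_equal(threshold_for_block(1, optimal_aim(1e-7, gf), 1e-7, gf), 1000)
  # composition with the quadrature oracle
  e_star <- optimal_aim(1, gf)
  expect_equal(threshold_for_block(0.925, e_star, 1, gf),
               round(10 * eg_trapezoid(0.925 * e_star, 1, gf)))
  # backing away from the optimum can only lower the expected total
  alphas <- seq(1, 0.8, by = -0.025)
  thresholds <- vapply(alphas, threshold_for_block, numeric(1),
                       e_star = e_star, sigma = 1, gf = gf)
  expect_true(all(diff(thresholds) <= 0))
  expect_error(threshold_for_block(1, 28, -1, gf), "positive")
  # threshold blocks in a run record the threshold and a win/loss outcome
  run <- run_experiment("exp5_threshold", 1, subject_model(), seed = 8)
  thr <- dplyr::filter(run$blocks, session == "threshold")
  expect_true(all(is.finite(thr$threshold)))
  expect_true(all(thr$winner %in% c("subject", "opponent")))
})
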