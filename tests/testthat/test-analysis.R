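make_table <- function(ai = 28.5, ac = 27.5, ao = 26.5, n_comp_blocks = 3) {
  base <- tidyr::expand_grid(subject_id = "s01", group = "toy",
                             session = "baseline", block = 1:5, trial = 1:10,
                             role = "subject", endpoint_cm = ai)
  comp <- tidyr::expand_grid(subject_id = "s01", group = "toy",
                             session = "competition",
                             block = 1:n_comp_blocks, trial = 1:10,
                             role = c("subject", "opponent"))
  comp$endpoint_cm <- ifelse(comp$role == "subject", ac, ao)
  out <- dplyr::bind_rows(base, comp)
  out$block <- as.integer(out$block)
  out$trial <- as.integer(out$trial)
  out$score <- gain(out$endpoint_cm)
  out$mistrial <- FALSE
  out
}

test_that("aim-point indices partition roles and windows correctly", {
  tab <- make_table()
  ap <- compute_aim_points(tab)
  expect_equal(nrow(ap), 3)
  expect_true(all(ap$A_i == 28.5))
  expect_true(all(ap$A_c == 27.5))   # opponent rows excluded
  expect_true(all(ap$A_o == 26.5))   # subject rows excluded
  expect_error(compute_aim_points(dplyr::filter(tab, session != "baseline")),
               "baseline")
  expect_error(
    compute_aim_points(dplyr::filter(tab, session != "competition")),
    "competition")
})

test_that("the last-50 baseline variant uses pre-competition trials only", {
  run <- run_experiment("exp1c", 1, subject_model(), seed = 2)
  ap <- compute_aim_points(run$trials, baseline = "last50")
  ind <- run$trials |>
    dplyr::filter(session %in% c("baseline", "individual"),
                  role == "subject")
  expect_equal(unique(ap$A_i), mean(utils::tail(ind$endpoint_cm, 50)))
  # differs from the early-baseline window when the aim drifts with practice
  ap0 <- compute_aim_points(run$trials)
  expect_false(isTRUE(all.equal(unique(ap0$A_i), unique(ap$A_i))))
})

test_that("relative aims yield one point per subject and kept block", {
  tab <- make_table()
  ra <- relative_aims(compute_aim_points(tab))
  expect_equal(nrow(ra), 2)          # block 1 excluded by default
  expect_equal(ra$x, c(-2, -2))
  expect_equal(ra$y, c(-1, -1))
  ra_all <- relative_aims(compute_aim_points(tab), blocks = 1:3)
  expect_equal(nrow(ra_all), 3)
  # an 8-subject 12-block cohort gives the study's 88 points
  trials <- generate_cohort("exp1b", 8, subject_model(), seed = 41)
  expect_equal(nrow(relative_aims(compute_aim_points(trials))), 88)
})

test_that("risk-sensitivity recovers the generating bias and its sign", {
  expect_equal(risk_sensitivity(28.2, 1.5), 28.2 - optimal_aim(1.5))
  m_pos <- subject_model(baseline_bias = 0.9, baseline_bias_sd = 0)
  m_neg <- subject_model(baseline_bias = -0.9, baseline_bias_sd = 0)
  rs_pos <- cohort_risk_sensitivity(
    generate_cohort("exp1a", 6, m_pos, seed = 10), "baseline")
  rs_neg <- cohort_risk_sensitivity(
    generate_cohort("exp1a", 6, m_neg, seed = 10), "baseline")
  # recovery within 3 SE of the generating bias (subjects are independent)
  se <- sd(rs_pos$risk_sensitivity) / sqrt(nrow(rs_pos))
  expect_lt(abs(mean(rs_pos$risk_sensitivity) - 0.9), 3 * se)
  expect_lt(abs(mean(rs_neg$risk_sensitivity) + 0.9), 3 * se)
  # antisymmetry is exact under a shared seed: flipping the bias shifts every
  # endpoint by a constant, leaving the variability estimate untouched
  expect_equal(rs_pos$risk_sensitivity - rs_neg$risk_sensitivity,
               rep(1.8, nrow(rs_pos)), tolerance = 1e-3)
  expect_error(cohort_risk_sensitivity(
    generate_cohort("exp1a", 1, m_pos, seed = 1), "competition",
    blocks = 99), "empty")
})

test_that("competition with a risk-averse opponent tempers risk-seeking", {
  trials <- generate_cohort("exp1b", 8, subject_model(), seed = 12)
  rs_base <- cohort_risk_sensitivity(trials, "baseline")
  rs_late <- cohort_risk_sensitivity(trials, "competition", blocks = 8:12)
  expect_gt(mean(rs_base$risk_sensitivity), 0)
  expect_lt(mean(rs_late$risk_sensitivity),
            mean(rs_base$risk_sensitivity))
})

test_that("split slopes fit each half exactly and reject thin sides", {
  x <- c(-3, -2, -1, -0.5, 0.5, 1, 2, 3)
  on_line <- tibble::tibble(x = x, y = 0.5 * x + 1)
  sl <- split_slopes(on_line)
  expect_equal(sl$slope, c(0.5, 0.5))
  expect_equal(sl$n, c(4, 4))
  # vertical translation only moves the intercepts
  shifted <- dplyr::mutate(on_line, y = y + 3)
  expect_equal(split_slopes(shifted)$slope, sl$slope)
  expect_equal(split_slopes(shifted)$intercept, sl$intercept + 3)
  expect_error(split_slopes(on_line[c(1, 2, 5:8), ]), "at least 3")
})

test_that("bootstrap slope test recovers generating slopes at n = 88", {
  set.seed(101)
  pts <- two_slope_points(n = 88, slope_neg = 0.2, slope_pos = 0.6,
                          noise = 0.3)
  st <- bootstrap_permutation_slopes(pts, n_boot = 4000, seed = 5)
  expect_true(st$ci_left[1] <= 0.2 && 0.2 <= st$ci_left[2])
  expect_true(st$ci_right[1] <= 0.6 && 0.6 <= st$ci_right[2])
  # point estimates sit inside their own bootstrap intervals
  expect_true(st$ci_left[1] <= st$slope_left &&
                st$slope_left <= st$ci_left[2])
  expect_true(st$ci_right[1] <= st$slope_right &&
                st$slope_right <= st$ci_right[2])
  expect_lt(st$p_perm, 0.05)
  # bit-reproducible under a seed
  st2 <- bootstrap_permutation_slopes(pts, n_boot = 4000, seed = 5)
  expect_identical(st$boot_left, st2$boot_left)
  expect_identical(st$p_perm, st2$p_perm)
  # tidy/glance accessors
  td <- tidy(st)
  expect_equal(td$estimate, c(st$slope_left, st$slope_right))
  expect_equal(glance(st)$p_perm, st$p_perm)
})

test_that("collinear points make the permutation count degenerate at 1", {
  x <- seq(-3, 3, length.out = 40)
  pts <- tibble::tibble(x = x, y = 0.5 * x + 1)
  st <- bootstrap_permutation_slopes(pts, n_boot = 500, seed = 3)
  expect_equal(st$p_perm, 1)          # every resample ties under >=
  st_gt <- bootstrap_permutation_slopes(pts, n_boot = 500, seed = 3,
                                        tie = "gt")
  expect_equal(st_gt$p_perm, 0)       # and never strictly exceeds
})

test_that("information criteria select the generating model class", {
  set.seed(61)
  x <- runif(187, -3, 1)
  quad <- tibble::tibble(x = x, y = 0.3 * x + 0.15 * x^2 + rnorm(187, 0, 0.3))
  fits <- fit_linear_quadratic(quad)
  expect_lt(fits$AICc[fits$model == "quadratic"],
            fits$AICc[fits$model == "linear"])
  # the documented Gaussian-likelihood AIC formula holds
  lin <- stats::lm(y ~ x, data = quad)
  rss <- sum(stats::resid(lin)^2)
  n <- nrow(quad)
  expect_equal(fits$AIC[fits$model == "linear"],
               n * log(rss / n) + n * log(2 * pi) + n + 2 * 3)
  # invariant to point order
  fits_shuffled <- fit_linear_quadratic(quad[sample(n), ])
  expect_equal(fits$AICc, fits_shuffled$AICc)
  expect_error(fit_linear_quadratic(quad[1:4, ]), "too few")
})

test_that("paired effect size follows the correlated-samples formula", {
  expect_equal(paired_cohens_d(1, 1, 1, 1, 0.5), 0)
  # r = 0 reduces to the independent-variances denominator
  expect_equal(paired_cohens_d(2, 0.8, 1, 0.6, 0),
               1 / sqrt(0.8^2 + 0.6^2))
  # simulation oracle: d equals mean difference over SD of differences
  set.seed(8)
  n <- 2e5
  z <- rnorm(n); e <- rnorm(n)
  x1 <- 1.0 + 0.65 * z
  x2 <- 0.0 + 0.70 * (0.4 * z + sqrt(1 - 0.4^2) * e)
  d_sim <- mean(x1 - x2) / sd(x1 - x2)
  expect_equal(paired_cohens_d(mean(x1), sd(x1), mean(x2), sd(x2),
                               cor(x1, x2)),
               d_sim, tolerance = 1e-6)
  expect_error(paired_cohens_d(1, 1, 0, 1, 1), "degenerate")
})

test_that("noncentral-t power iteration matches a simulation oracle", {
  # power is monotone in n
  pw <- vapply(2:50, power_paired_t, numeric(1), d = 0.8)
  expect_true(all(diff(pw) >= -1e-12))
  # Monte-Carlo oracle at small n
  set.seed(19)
  d <- 1.2; n <- 8
  rej <- mean(replicate(4000, {
    x <- rnorm(n, d, 1)
    stats::t.test(x)$p.value < 0.05
  }))
  expect_equal(power_paired_t(n, d), rej, tolerance = 0.03)
  # exhaustive small-n check for a huge effect
  pw10 <- vapply(2:10, power_paired_t, numeric(1), d = 10)
  expect_equal(required_sample_size(10), 1 + which(pw10 >= 0.80)[1])
  expect_error(required_sample_size(1e-4, max_n = 50), "unattainable")
})

test_that("t-test wrappers report calibrated p-values and CI duality", {
  set.seed(33)
  # null calibration: p approximately uniform
  ps <- replicate(400, one_sample_t_test(rnorm(10))$p_value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # CI excludes 0 exactly when p < 0.05
  res <- purrr::map_dfr(1:200, function(i) {
    paired_t_test(rnorm(8, 0.5), rnorm(8))
  })
  excluded <- res$conf_low > 0 | res$conf_high < 0
  expect_equal(excluded, res$p_value < 0.05)
  expect_error(paired_t_test(1:5, 1:5), "degenerate")
  expect_error(one_sample_t_test(rep(2, 5)), "degenerate")
})
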