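#' Aim-point indices per subject and competitive block
#'
#' Computes the study's three aim-point measures from a trial table:
#' `A_i`, the subject's mean endpoint in the individual task (by default the
#' 50 baseline trials; optionally the last 50 individual-task trials before
#' competition started); `A_c`, the subject's mean endpoint in each
#' competitive block; and `A_o`, the opponent's mean endpoint in each
#' competitive block.
#'
#' @param trials A trial table (see [generate_cohort()] /
#'   [read_trial_table()]).
#' @param baseline `"baseline_session"` (default) to take `A_i` over the
#'   baseline session, or `"last50"` to take the last 50 individual-task
#'   trials preceding the first competitive trial.
#' @return A tibble with one row per subject x competitive block:
#'   `subject_id`, `group`, `block`, `A_i`, `A_c`, `A_o`.
#' @export
compute_aim_points <- function(trials,
                               baseline = c("baseline_session", "last50")) {
  baseline <- match.arg(baseline)
  if (!"competition" %in% trials$session) {
    stop("trial table has no competition session.", call. = FALSE)
  }
  individual_sessions <- c("baseline", "individual", "washout")
  ai <- if (baseline == "baseline_session") {
    if (!"baseline" %in% trials$session) {
      stop("trial table has no baseline session.", call. = FALSE)
    }
    trials |>
      dplyr::filter(.data$session == "baseline", .data$role == "subject") |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(A_i = mean(.data$endpoint_cm), .groups = "drop")
  } else {
    trials |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_modify(function(df, key) {
        first_comp <- which(df$session == "competition")[1]
        if (is.na(first_comp)) {
          stop("subject without competition trials.", call. = FALSE)
        }
        pre <- df[seq_len(first_comp - 1L), ]
        pre <- pre[pre$session %in% individual_sessions &
                     pre$role == "subject", ]
        tibble::tibble(A_i = mean(utils::tail(pre$endpoint_cm, 50)))
      }) |>
      dplyr::ungroup()
  }
  comp <- trials |>
    dplyr::filter(.data$session == "competition") |>
    dplyr::group_by(.data$subject_id, .data$group, .data$block) |>
    dplyr::summarise(
      A_c = mean(.data$endpoint_cm[.data$role == "subject"]),
      A_o = mean(.data$endpoint_cm[.data$role == "opponent"]),
      .groups = "drop")
  dplyr::left_join(comp, ai, by = "subject_id") |>
    dplyr::select("subject_id", "group", "block", "A_i", "A_c", "A_o")
}

#' Risk-sensitivity of an observed mean endpoint
#'
#' Risk-sensitivity is the deviation of the actual aim point (observed mean
#' endpoint) from the optimal aim point for the observed variability:
#' positive values are risk-seeking, negative risk-averse, zero risk-neutral.
#'
#' @param mean_endpoint Observed mean endpoint in cm.
#' @param sigma Observed endpoint SD in cm, > 0.
#' @param gf A [gain_function()].
#' @return Risk-sensitivity in cm.
#' @examples
#' risk_sensitivity(28.2, 1.5)  # aiming above the optimum: risk-seeking
#' @export
risk_sensitivity <- function(mean_endpoint, sigma, gf = gain_function()) {
  mean_endpoint - optimal_aim(sigma, gf)
}

#' Per-subject risk-sensitivity over a trial window
#'
#' Applies [risk_sensitivity()] to each subject's trials in a window: the
#' baseline session, or a range of competitive blocks (the study uses blocks
#' 8-12, the last 50 competitive trials). The optimal aim point is computed
#' from the subject's own endpoint SD within the window.
#'
#' @param trials A trial table.
#' @param window `"baseline"` or `"competition"`.
#' @param blocks Competitive blocks to pool when `window = "competition"`
#'   (default `8:12`).
#' @param gf A [gain_function()].
#' @param min_trials Windows with fewer subject trials than this are refused
#'   (default 10).
#' @return A tibble with one row per subject: observed mean, SD, optimal aim
#'   and `risk_sensitivity` (cm).
#' @export
cohort_risk_sensitivity <- function(trials,
                                    window = c("baseline", "competition"),
                                    blocks = 8:12, gf = gain_function(),
                                    min_trials = 10) {
  window <- match.arg(window)
  sel <- if (window == "baseline") {
    dplyr::filter(trials, .data$session == "baseline",
                  .data$role == "subject")
  } else {
    dplyr::filter(trials, .data$session == "competition",
                  .data$role == "subject", .data$block %in% blocks)
  }
  if (nrow(sel) == 0) stop("empty trial window.", call. = FALSE)
  out <- sel |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     mean_endpoint = mean(.data$endpoint_cm),
                     sigma_hat = stats::sd(.data$endpoint_cm),
                     .groups = "drop")
  if (any(out$n_trials < min_trials)) {
    stop("risk-sensitivity window has fewer than `min_trials` trials.",
         call. = FALSE)
  }
  out |>
    dplyr::mutate(window = window,
                  e_star = optimal_aim(.data$sigma_hat, gf),
                  risk_sensitivity = .data$mean_endpoint - .data$e_star)
}

#' Relative aim points (the non-linearity scatter)
#'
#' For each subject and competitive block, computes the opponent's relative
#' aim `x = A_o - A_i` and the subject's relative aim `y = A_c - A_i`. The
#' first competitive block is excluded by default (the transient inhibition
#' makes it unrepresentative), leaving blocks 2-12.
#'
#' @param aim_points Output of [compute_aim_points()].
#' @param blocks Blocks to keep (default `2:12`).
#' @return A tibble with `subject_id`, `group`, `block`, `x`, `y`.
#' @export
relative_aims <- function(aim_points, blocks = 2:12) {
  aim_points |>
    dplyr::filter(.data$block %in% blocks) |>
    dplyr::transmute(.data$subject_id, .data$group, .data$block,
                     x = .data$A_o - .data$A_i,
                     y = .data$A_c - .data$A_i)
}

ols_slope <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  den <- sum(x * x) - sx * sx / n
  if (den <= 0) return(NA_real_)
  (sum(x * y) - sx * sy / n) / den
}

#' Regression slopes of the two halves of the relative-aim plane
#'
#' Fits ordinary least squares (with intercept) separately to the points with
#' `x < split_at` (opponents aiming below the subject's individual-task aim)
#' and `x >= split_at` (above). Different slopes indicate a non-linear
#' influence of the opponent's decisions.
#'
#' @param points A data frame with columns `x` and `y` (see
#'   [relative_aims()]).
#' @param split_at Split point on `x` (default 0).
#' @return A tibble with one row per side: `side`, `n`, `slope`, `intercept`.
#' @export
split_slopes <- function(points, split_at = 0) {
  left <- points[points$x < split_at, ]
  right <- points[points$x >= split_at, ]
  if (nrow(left) < 3 || nrow(right) < 3) {
    stop(sprintf(
      "need at least 3 points on each side of x = %g (have %d left, %d right).",
      split_at, nrow(left), nrow(right)), call. = FALSE)
  }
  fit <- function(df, side) {
    sl <- ols_slope(df$x, df$y)
    tibble::tibble(side = side, n = nrow(df), slope = sl,
                   intercept = mean(df$y) - sl * mean(df$x))
  }
  dplyr::bind_rows(fit(left, "left"), fit(right, "right"))
}

# slopes of both halves for resampled columns of an index matrix, vectorised
boot_slopes_matrix <- function(x, y, idx, split_at) {
  xb <- matrix(x[idx], nrow = nrow(idx))
  yb <- matrix(y[idx], nrow = nrow(idx))
  side_slope <- function(mask) {
    m <- colSums(mask)
    sx <- colSums(xb * mask); sy <- colSums(yb * mask)
    sxx <- colSums(xb * xb * mask); sxy <- colSums(xb * yb * mask)
    den <- sxx - sx * sx / m
    slope <- (sxy - sx * sy / m) / den
    list(n = m, den = den, slope = slope)
  }
  l <- side_slope(xb < split_at)
  r <- side_slope(xb >= split_at)
  bad <- l$n < 3 | r$n < 3 | !is.finite(l$slope) | !is.finite(r$slope) |
    l$den <= 1e-12 | r$den <= 1e-12
  list(left = l$slope, right = r$slope, bad = bad)
}

#' Bootstrap and permutation comparison of the two half-plane slopes
#'
#' Resamples the pooled points with replacement (same n) `n_boot` times; for
#' each resample both half-plane slopes are refit. The permutation p-value is
#' the fraction of resamples in which the left-half slope is at least as
#' large as the right-half slope (`tie = "geq"`, the conservative reading of
#' "larger than"; `tie = "gt"` counts strict exceedances). Resamples leaving
#' fewer than 3 points on a side are redrawn and counted.
#'
#' @param points A data frame with columns `x` and `y`.
#' @param n_boot Number of bootstrap resamples (default 50000).
#' @param split_at Split point on `x` (default 0).
#' @param tie `"geq"` or `"gt"` tie rule for the permutation count.
#' @param seed Optional integer seed for reproducibility.
#' @param chunk Resamples per vectorised chunk (memory knob; default 5000).
#' @return An object of class `slope_test`: point estimates, bootstrap
#'   distributions, 95% percentile CIs, `p_perm`, and the redraw count.
#'   Use [tidy()] / [glance()] or `print()` to inspect it.
#' @export
bootstrap_permutation_slopes <- function(points, n_boot = 50000,
                                         split_at = 0,
                                         tie = c("geq", "gt"), seed = NULL,
                                         chunk = 5000) {
  tie <- match.arg(tie)
  est <- split_slopes(points, split_at)   # also validates the preconditions
  if (!is.null(seed)) set.seed(seed)
  x <- points$x; y <- points$y; n <- length(x)
  boot_l <- numeric(n_boot); boot_r <- numeric(n_boot)
  done <- 0L; redrawn <- 0L
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
    res <- boot_slopes_matrix(x, y, idx, split_at)
    tries <- 0L
    while (any(res$bad) && tries < 1000L) {
      k <- which(res$bad)
      redrawn <- redrawn + length(k)
      idx[, k] <- sample.int(n, n * length(k), replace = TRUE)
      res <- boot_slopes_matrix(x, y, idx, split_at)
      tries <- tries + 1L
    }
    if (any(res$bad)) {
      stop("could not draw non-degenerate bootstrap resamples.",
           call. = FALSE)
    }
    boot_l[done + seq_len(b)] <- res$left
    boot_r[done + seq_len(b)] <- res$right
    done <- done + b
  }
  # numerically identical slopes count as ties
  eps <- 1e-10 * pmax(1, abs(boot_r))
  p_perm <- if (tie == "geq") mean(boot_l >= boot_r - eps)
            else mean(boot_l > boot_r + eps)
  structure(list(
    slope_left = est$slope[est$side == "left"],
    slope_right = est$slope[est$side == "right"],
    n_left = est$n[est$side == "left"], n_right = est$n[est$side == "right"],
    boot_left = boot_l, boot_right = boot_r,
    ci_left = unname(stats::quantile(boot_l, c(0.025, 0.975))),
    ci_right = unname(stats::quantile(boot_r, c(0.025, 0.975))),
    p_perm = p_perm, n_boot = n_boot, n_redrawn = redrawn,
    tie = tie, split_at = split_at), class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf(paste0(
    "<slope_test> split at x = %g, %d resamples (%d redrawn)\n",
    "  left  (n = %d): slope %.3f, 95%% CI [%.3f, %.3f]\n",
    "  right (n = %d): slope %.3f, 95%% CI [%.3f, %.3f]\n",
    "  permutation p (left %s right) = %.4g\n"),
    x$split_at, x$n_boot, x$n_redrawn,
    x$n_left, x$slope_left, x$ci_left[1], x$ci_left[2],
    x$n_right, x$slope_right, x$ci_right[1], x$ci_right[2],
    if (x$tie == "geq") ">=" else ">", x$p_perm))
  invisible(x)
}

#' Linear versus quadratic fit of the relative-aim scatter
#'
#' Fits `y ~ x` and `y ~ x + x^2` by least squares and reports
#' Gaussian-likelihood information criteria (AIC, BIC, AICc, with the full
#' constant terms so magnitudes are comparable across software) and adjusted
#' R-squared. `k` counts the regression coefficients plus the residual
#' variance.
#'
#' @param points A data frame with columns `x` and `y`.
#' @return A tibble with one row per model: `model`, `n`, `k`, `AIC`, `BIC`,
#'   `AICc`, `adj_R2`, and a list-column `coefficients`.
#' @export
fit_linear_quadratic <- function(points) {
  n <- nrow(points)
  fits <- list(linear = stats::lm(y ~ x, data = points),
               quadratic = stats::lm(y ~ x + I(x^2), data = points))
  purrr::imap_dfr(fits, function(fit, name) {
    k <- length(stats::coef(fit)) + 1L   # + residual variance
    if (n <= k + 2L) {
      stop("too few points for AICc (need n > k + 2).", call. = FALSE)
    }
    if (any(!is.finite(stats::coef(fit)))) {
      stop("singular design in ", name, " fit.", call. = FALSE)
    }
    tibble::tibble(model = name, n = n, k = k,
                   AIC = stats::AIC(fit), BIC = stats::BIC(fit),
                   AICc = stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1),
                   adj_R2 = summary(fit)$adj.r.squared,
                   coefficients = list(stats::coef(fit)))
  })
}

#' Paired-samples Cohen's d from summary statistics
#'
#' Effect size for two paired samples computed from their means, standard
#' deviations and correlation:
#' \eqn{d = (m_1 - m_2) / \sqrt{s_1^2 + s_2^2 - 2 r s_1 s_2}}, i.e. the mean
#' difference standardised by the SD of the paired differences.
#'
#' @param m1,s1 Mean and SD of the first sample.
#' @param m2,s2 Mean and SD of the second sample.
#' @param r Correlation between the paired samples, in `[-1, 1]`.
#' @return Cohen's d (dimensionless).
#' @examples
#' paired_cohens_d(1.15, 0.65, -0.01, 0.70, 0.38)
#' @export
paired_cohens_d <- function(m1, s1, m2, s2, r) {
  stopifnot(s1 > 0, s2 > 0, abs(r) <= 1)
  v <- s1^2 + s2^2 - 2 * r * s1 * s2
  if (v <= 0) stop("degenerate pairing: zero difference variance.",
                   call. = FALSE)
  (m1 - m2) / sqrt(v)
}

#' Power of a paired (one-sample) t-test
#'
#' Exact power via the noncentral t distribution: with `n` pairs, effect size
#' `d`, and a two-tailed (or one-tailed) critical value at `alpha`, the power
#' is the probability that `|t|` exceeds the critical value when the
#' noncentrality is `d * sqrt(n)`.
#'
#' @param n Number of pairs (>= 2).
#' @param d Effect size (Cohen's d of the paired differences).
#' @param alpha Significance level (default 0.05).
#' @param tails 2 (default) or 1.
#' @return Power in `[0, 1]`.
#' @export
power_paired_t <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- n - 1
  ncp <- d * sqrt(n)
  crit <- stats::qt(1 - alpha / tails, df)
  pw <- 1 - stats::pt(crit, df, ncp)
  if (tails == 2) pw <- pw + stats::pt(-crit, df, ncp)
  pw
}

#' Minimum sample size for a paired t-test
#'
#' Smallest integer `n >= 2` whose exact noncentral-t power reaches the
#' target, scanning candidate sample sizes upward.
#'
#' @param d Effect size, > 0.
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param tails 2 (default) or 1.
#' @param max_n Search bound (default 1e6).
#' @return Required number of pairs.
#' @examples
#' required_sample_size(1.54)  # 6
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.80, tails = 2,
                                 max_n = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:max_n) {
    if (power_paired_t(n, d, alpha, tails) >= power) return(n)
  }
  stop("power target unattainable within `max_n` pairs.", call. = FALSE)
}

t_result <- function(ht, d) {
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_diff = unname(ht$estimate),
                 conf_low = ht$conf.int[1], conf_high = ht$conf.int[2],
                 cohens_d = d)
}

#' Two-tailed paired-sample t-test with effect size
#'
#' Wraps [stats::t.test()] (paired) and reports the effect size as the mean
#' difference over the SD of the differences.
#'
#' @param x,y Paired numeric samples of equal length (n >= 2).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_diff`,
#'   `conf_low`, `conf_high`, `cohens_d`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  diffs <- x - y
  if (stats::sd(diffs) == 0) {
    stop("degenerate pairing: all differences identical.", call. = FALSE)
  }
  t_result(stats::t.test(x, y, paired = TRUE),
           mean(diffs) / stats::sd(diffs))
}

#' Two-tailed one-sample t-test with effect size
#'
#' @param x Numeric sample (n >= 2).
#' @param mu Null value (default 0).
#' @return A one-row tibble as in [paired_t_test()]; `mean_diff` is the
#'   sample mean minus `mu`.
#' @export
one_sample_t_test <- function(x, mu = 0) {
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0) {
    stop("degenerate sample: zero variance.", call. = FALSE)
  }
  out <- t_result(stats::t.test(x, mu = mu), (mean(x) - mu) / stats::sd(x))
  out$mean_diff <- mean(x) - mu
  out
}
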