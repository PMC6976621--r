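#' Virtual-opponent schedule
#'
#' The computer opponent draws each endpoint from
#' \eqn{N(\alpha E^*(\hat\sigma), \hat\sigma^2)}, where \eqn{\hat\sigma} is
#' the player's own recent endpoint variability and \eqn{\alpha} scales the
#' opponent's risk attitude: \eqn{\alpha = 1} is the risk-neutral optimum,
#' \eqn{\alpha < 1} aims short of it (risk-averse). A schedule fixes one
#' \eqn{\alpha} per competitive block and says how \eqn{\hat\sigma} is
#' obtained.
#'
#' Presets:
#' * `exp1a` — risk-neutral: alpha = 1 for all 12 blocks.
#' * `exp1b` — risk-averse: alpha = 1 for blocks 1-4, then declining to 0.925
#'   at block 9 (steps of 0.015) and 0.925 for blocks 9-12.
#' * `exp1c` — alpha = 1 for the 4 competitive blocks after extended practice.
#' * `exp2` — alpha = 1 for all 12 blocks (opponent previewed beforehand).
#' * `exp4` — highly risk-averse: alpha = 0.925 throughout, with the
#'   opponent's sigma frozen at the player's baseline variability.
#' * `exp5_observation`, `exp5_threshold` — the `exp1b` alpha sequence reused
#'   by the observation and threshold tasks.
#'
#' @param preset Name of a preset schedule (see Details), or `NULL` to supply
#'   `alpha` directly.
#' @param alpha Numeric vector of per-block risk coefficients, all positive.
#' @param sigma_mode `"rolling_40"` (re-estimate from the player's last 40
#'   reaches before each block) or `"frozen_baseline"` (fixed at the
#'   variability of the last 40 baseline reaches).
#' @return An object of class `opponent_schedule`.
#' @examples
#' opponent_schedule("exp1b")
#' @export
opponent_schedule <- function(preset = NULL, alpha = NULL,
                              sigma_mode = c("rolling_40", "frozen_baseline")) {
  sigma_mode_given <- !missing(sigma_mode)
  sigma_mode <- match.arg(sigma_mode)
  alpha_1b <- c(rep(1, 4), 1 - 0.015 * (1:4), rep(0.925, 4))
  if (!is.null(preset)) {
    presets <- list(
      exp1a = list(alpha = rep(1, 12), sigma_mode = "rolling_40"),
      exp1b = list(alpha = alpha_1b, sigma_mode = "rolling_40"),
      exp1c = list(alpha = rep(1, 4), sigma_mode = "rolling_40"),
      exp2  = list(alpha = rep(1, 12), sigma_mode = "rolling_40"),
      exp4  = list(alpha = rep(0.925, 12), sigma_mode = "frozen_baseline"),
      exp5_observation = list(alpha = alpha_1b, sigma_mode = "rolling_40"),
      exp5_threshold   = list(alpha = alpha_1b, sigma_mode = "rolling_40")
    )
    if (!preset %in% names(presets)) {
      stop("unknown opponent schedule preset: ", preset, call. = FALSE)
    }
    sched <- presets[[preset]]
    if (!is.null(alpha)) sched$alpha <- alpha
    if (sigma_mode_given) sched$sigma_mode <- sigma_mode
    alpha <- sched$alpha
    sigma_mode <- sched$sigma_mode
  }
  if (is.null(alpha) || !is.numeric(alpha) || any(alpha <= 0)) {
    stop("`alpha` must be a positive numeric vector.", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), sigma_mode = sigma_mode,
                 preset = preset %||% "custom"),
            class = "opponent_schedule")
}

#' @export
print.opponent_schedule <- function(x, ...) {
  cat(sprintf("<opponent_schedule> %s: %d blocks, sigma %s\n  alpha: %s\n",
              x$preset, length(x$alpha), x$sigma_mode,
              paste(format(x$alpha, digits = 3), collapse = " ")))
  invisible(x)
}

#' Synthetic subject model
#'
#' Parameterises a synthetic human player with the statistical structure the
#' analysis pipeline is built to detect. It is a generative stand-in, not a
#' cognitive model: at baseline the subject aims a fixed bias above the
#' optimal aim point (risk-seeking); on entering competition the aim is
#' transiently inhibited over the first few trials; and across competitive
#' blocks the aim responds to the opponent's relative aim with two slopes,
#' steeper for opponents aiming above the subject's baseline than below.
#'
#' @param baseline_bias Risk-sensitivity b in cm: baseline aim is
#'   `E* + baseline_bias`. Positive = risk-seeking. Default 1.0.
#' @param baseline_bias_sd Between-subject SD of the bias in cm, used by the
#'   cohort generator to draw one bias per subject. Default 0.65.
#' @param sigma0 Motor SD in cm at the start of the session. Default 1.5.
#' @param sigma_decay Per-block multiplicative shrink of the motor SD from
#'   practice (default 0.98; about a 0.73x reduction over a 22-block session).
#'   Set to 1 for no practice effect.
#' @param sigma_floor Lower bound on the motor SD in cm. Default 0.5.
#' @param inhibition Size of the initial competitive aim decrease in cm
#'   (default 1.0), applied in the first competitive block only.
#' @param inhibition_decay_trials Number of trials over which the inhibition
#'   decays linearly to zero (default 5).
#' @param slope_pos Response slope when the opponent's relative aim is >= 0
#'   (default 0.63).
#' @param slope_neg Response slope when the opponent's relative aim is < 0
#'   (default 0.21).
#' @param response_noise Block-to-block SD of aim jitter in cm (default 0.3).
#' @return An object of class `subject_model`.
#' @examples
#' subject_model(baseline_bias = 0.7)
#' @export
subject_model <- function(baseline_bias = 1.0, baseline_bias_sd = 0.65,
                          sigma0 = 1.5, sigma_decay = 0.98, sigma_floor = 0.5,
                          inhibition = 1.0, inhibition_decay_trials = 5,
                          slope_pos = 0.63, slope_neg = 0.21,
                          response_noise = 0.3) {
  stopifnot(sigma0 > 0, sigma_floor > 0, sigma_decay > 0, sigma_decay <= 1,
            inhibition >= 0, inhibition_decay_trials >= 1,
            baseline_bias_sd >= 0, response_noise >= 0)
  structure(list(baseline_bias = baseline_bias,
                 baseline_bias_sd = baseline_bias_sd,
                 sigma0 = sigma0, sigma_decay = sigma_decay,
                 sigma_floor = sigma_floor,
                 inhibition = inhibition,
                 inhibition_decay_trials = inhibition_decay_trials,
                 slope_pos = slope_pos, slope_neg = slope_neg,
                 response_noise = response_noise),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<subject_model> bias %.2f cm (SD %.2f), sigma0 %.2f cm (decay %.3f/block),\n",
    "  inhibition %.2f cm over %d trials, slopes %.2f (opp below) / %.2f (opp above),\n",
    "  aim jitter %.2f cm\n"),
    x$baseline_bias, x$baseline_bias_sd, x$sigma0, x$sigma_decay,
    x$inhibition, x$inhibition_decay_trials, x$slope_neg, x$slope_pos,
    x$response_noise))
  invisible(x)
}

#' Endpoint variability over a trailing window
#'
#' Sample standard deviation (n - 1 denominator) of the last `window`
#' endpoints, as used to set the virtual opponent's accuracy before each
#' competitive block.
#'
#' @param endpoints Numeric vector of endpoints in cm, in trial order.
#' @param window Number of trailing trials to use (default 40).
#' @return Standard deviation in cm.
#' @examples
#' estimate_sigma(rnorm(60, 28, 1.5))
#' @export
estimate_sigma <- function(endpoints, window = 40) {
  if (length(endpoints) < window) {
    stop(sprintf("insufficient history: need %d endpoints, have %d.",
                 window, length(endpoints)), call. = FALSE)
  }
  stats::sd(utils::tail(endpoints, window))
}

#' Sample virtual-opponent endpoints
#'
#' Draws endpoints from \eqn{N(\alpha E^*, \sigma^2)}: the opponent aims at
#' the scaled optimal aim point with the same accuracy as the player.
#'
#' @param alpha Opponent risk coefficient (dimensionless, > 0).
#' @param e_star Optimal aim point E* in cm.
#' @param sigma Endpoint SD in cm; must be strictly positive (a zero-variance
#'   opponent is degenerate and rejected).
#' @param n Number of draws (default 1).
#' @return Numeric vector of endpoints in cm.
#' @export
sample_opponent_endpoint <- function(alpha, e_star, sigma, n = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("opponent `sigma` must be a single positive number.", call. = FALSE)
  }
  stopifnot(alpha > 0, is.finite(e_star))
  stats::rnorm(n, mean = alpha * e_star, sd = sigma)
}

#' Aim point of a synthetic subject for one trial
#'
#' Deterministic core of the subject model. In individual-task blocks
#' (`opp_relative_aim = NULL`) the aim is `e_star + baseline_bias + jitter`.
#' In competitive blocks the aim additionally shifts by
#' `slope(x) * x` where `x` is the opponent's aim relative to the subject's
#' baseline aim (`slope_pos` for `x >= 0`, `slope_neg` for `x < 0`), and, in
#' the first competitive block only, is lowered by the inhibition term
#' `inhibition * max(0, 1 - (trial_index - 1)/inhibition_decay_trials)`.
#'
#' @param model A [subject_model()].
#' @param e_star Reference optimal aim point in cm.
#' @param opp_relative_aim Opponent aim minus the subject's baseline aim, in
#'   cm, or `NULL` outside competition.
#' @param block_index 1-based competitive block index (drives the inhibition
#'   window); use 1 for individual blocks.
#' @param trial_index 1-based trial index within the block.
#' @param jitter Block-level aim jitter in cm to add (default 0; the
#'   simulator draws it from `N(0, response_noise^2)`).
#' @return Aim point in cm.
#' @examples
#' m <- subject_model(inhibition = 0)
#' subject_block_aim(m, e_star = 27.1, opp_relative_aim = -2, block_index = 2,
#'                   trial_index = 1)  # 27.1 + 1 + 0.21 * (-2)
#' @export
subject_block_aim <- function(model, e_star, opp_relative_aim = NULL,
                              block_index = 1, trial_index = 1, jitter = 0) {
  stopifnot(inherits(model, "subject_model"), block_index >= 1,
            trial_index >= 1)
  aim <- e_star + model$baseline_bias + jitter
  if (!is.null(opp_relative_aim)) {
    x <- opp_relative_aim
    slope <- ifelse(x >= 0, model$slope_pos, model$slope_neg)
    aim <- aim + slope * x
    if (block_index == 1) {
      decay <- pmax(0, 1 - (trial_index - 1) / model$inhibition_decay_trials)
      aim <- aim - model$inhibition * decay
    }
  }
  aim
}
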