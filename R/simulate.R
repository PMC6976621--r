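trial_cols <- function() {
  tibble::tibble(subject_id = character(), group = character(),
                 session = character(), block = integer(), trial = integer(),
                 role = character(), endpoint_cm = double(), score = double(),
                 mistrial = logical())
}

block_cols <- function() {
  tibble::tibble(subject_id = character(), group = character(),
                 session = character(), block = integer(), alpha = double(),
                 sigma_true = double(), sigma_hat = double(),
                 E_star = double(), A = double(), A_o = double(),
                 subject_total = double(), opponent_total = double(),
                 threshold = double(), winner = character())
}

score_trials <- function(endpoints, gf) {
  e <- round(endpoints, 4)  # endpoints are logged at 0.1 um resolution
  tibble::tibble(endpoint_cm = e, score = gain(e, gf),
                 mistrial = e > gf$boundary | e <= gf$dead_zone)
}

#' Simulate one individual-task block
#'
#' Ten reaches at a fixed aim with Gaussian endpoint noise, scored by the
#' gain function. `sigma = 0` is allowed here (a deterministic reacher), which
#' is convenient for exact checks.
#'
#' @param aim Aim point in cm (length 1, or one per trial).
#' @param sigma Motor SD in cm, >= 0.
#' @param gf A [gain_function()].
#' @param n_trials Trials in the block (default 10).
#' @param subject_id,session,block Identity fields stamped on the records.
#' @return A tibble of trial records (`role = "subject"`).
#' @export
run_individual_block <- function(aim, sigma, gf = gain_function(),
                                 n_trials = 10, subject_id = "s1",
                                 session = "individual", block = 1L) {
  stopifnot(sigma >= 0, n_trials >= 1)
  aims <- rep_len(aim, n_trials)
  e <- stats::rnorm(n_trials, aims, sigma)
  dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, group = "custom",
                   session = session, block = as.integer(block),
                   trial = seq_len(n_trials), role = "subject"),
    score_trials(e, gf)
  )
}

#' Simulate one competitive block against the virtual opponent
#'
#' The opponent's accuracy is estimated from the subject's trailing 40
#' endpoints (`history`), its aim set to `alpha * E*(sigma_hat)`, and both
#' players' reaches are drawn and scored. Roles strictly alternate, subject
#' first, as in the live task.
#'
#' @param subject_aim Subject aim in cm (length 1 or `n_trials`).
#' @param subject_sigma Subject motor SD in cm, > 0.
#' @param alpha Opponent risk coefficient.
#' @param history Numeric vector of at least 40 prior subject endpoints.
#' @param gf A [gain_function()].
#' @param n_trials Trials per role (default 10).
#' @param subject_id,block Identity fields stamped on the records.
#' @return A list with `trials` (tibble, alternating roles) and `summary`
#'   (one-row tibble with means, totals and the block winner).
#' @export
run_competitive_block <- function(subject_aim, subject_sigma, alpha, history,
                                  gf = gain_function(), n_trials = 10,
                                  subject_id = "s1", block = 1L) {
  stopifnot(subject_sigma > 0, alpha > 0)
  sigma_hat <- estimate_sigma(history, 40)
  if (sigma_hat <= 0) {
    stop("degenerate opponent: estimated sigma is 0.", call. = FALSE)
  }
  e_star <- optimal_aim(sigma_hat, gf)
  aims <- rep_len(subject_aim, n_trials)
  e_s <- stats::rnorm(n_trials, aims, subject_sigma)
  e_o <- sample_opponent_endpoint(alpha, e_star, sigma_hat, n_trials)
  sub <- dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, group = "custom",
                   session = "competition", block = as.integer(block),
                   trial = seq_len(n_trials), role = "subject"),
    score_trials(e_s, gf))
  opp <- dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, group = "custom",
                   session = "competition", block = as.integer(block),
                   trial = seq_len(n_trials), role = "opponent"),
    score_trials(e_o, gf))
  idx <- rep(seq_len(n_trials), each = 2L) + c(0L, n_trials)
  trials <- dplyr::bind_rows(sub, opp)[idx, ]
  st <- sum(sub$score); ot <- sum(opp$score)
  summary <- tibble::tibble(
    subject_id = subject_id, group = "custom", session = "competition",
    block = as.integer(block), alpha = alpha, sigma_true = subject_sigma,
    sigma_hat = sigma_hat, E_star = e_star,
    A = mean(sub$endpoint_cm), A_o = mean(opp$endpoint_cm),
    subject_total = st, opponent_total = ot, threshold = NA_real_,
    winner = if (st > ot) "subject" else if (ot > st) "opponent" else "tie")
  list(trials = trials, summary = summary)
}

#' Expected block total of the risk-averse opponent (threshold task)
#'
#' The threshold task asks the player to exceed the total score a virtual
#' opponent with risk coefficient `alpha` would be expected to collect over a
#' block: `n_trials * EG(alpha * E*, sigma)`, rounded to the nearest integer
#' point (scores are displayed as integers).
#'
#' @param alpha Opponent risk coefficient.
#' @param e_star Optimal aim point in cm.
#' @param sigma Endpoint SD in cm, > 0.
#' @param gf A [gain_function()].
#' @param n_trials Trials per block (default 10).
#' @return Threshold total score in points.
#' @examples
#' threshold_for_block(0.925, optimal_aim(1), 1)
#' @export
threshold_for_block <- function(alpha, e_star, sigma, gf = gain_function(),
                                n_trials = 10) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be positive.", call. = FALSE)
  }
  round(n_trials * expected_gain(alpha * e_star, sigma, gf))
}

# One subject through a full protocol. `model` must already carry this
# subject's own baseline bias; the RNG state is the caller's responsibility.
# Hot path: accumulates plain vectors and builds the tibbles once.
simulate_subject <- function(proto, model, subject_id, gf) {
  n_tr <- proto$n_trials
  ses <- proto$sessions
  rows_per_block <- ifelse(ses$session %in% c("competition", "observation"),
                           2L * n_tr, n_tr)
  n_rows <- sum(rows_per_block * ses$n_blocks)
  nb <- sum(ses$n_blocks)

  t_sess <- character(n_rows); t_blk <- integer(n_rows)
  t_tr <- integer(n_rows); t_role <- character(n_rows)
  t_ep <- numeric(n_rows); t_sc <- numeric(n_rows)
  ti <- 0L

  b_sess <- character(nb); b_blk <- integer(nb)
  b_alpha <- rep(NA_real_, nb); b_strue <- rep(NA_real_, nb)
  b_shat <- rep(NA_real_, nb); b_estar <- rep(NA_real_, nb)
  b_A <- rep(NA_real_, nb); b_Ao <- rep(NA_real_, nb)
  b_st <- rep(NA_real_, nb); b_ot <- rep(NA_real_, nb)
  b_thr <- rep(NA_real_, nb); b_win <- rep(NA_character_, nb)
  bi <- 0L

  history <- numeric(0)       # the subject's own endpoints, in trial order
  k <- 0L                     # cumulative practice blocks (drives sigma decay)
  opp_i <- 0L                 # index into the opponent alpha schedule
  comp_j <- 0L                # competitive block counter (inhibition window)
  sigma_base40 <- NA_real_    # frozen-baseline opponent sigma
  ref <- NA_real_             # subject's measured baseline aim (mean endpoint)
  n_base <- 0L                # baseline reaches accumulated

  for (si in seq_len(nrow(ses))) {
    session <- ses$session[si]
    n_blocks <- ses$n_blocks[si]
    for (j in seq_len(n_blocks)) {
      bi <- bi + 1L
      b_sess[bi] <- session; b_blk[bi] <- j

      if (session == "presentation") {
        # opponent-only preview: 10 risk-neutral reaches, no subject practice
        sigma_hat <- estimate_sigma(history, 40)
        e_star <- optimal_aim(sigma_hat, gf)
        e_o <- round(sample_opponent_endpoint(1, e_star, sigma_hat, n_tr), 4)
        idx <- ti + seq_len(n_tr); ti <- ti + n_tr
        t_sess[idx] <- session; t_blk[idx] <- j; t_tr[idx] <- seq_len(n_tr)
        t_role[idx] <- "opponent"; t_ep[idx] <- e_o
        t_sc[idx] <- gain(e_o, gf)
        b_alpha[bi] <- 1; b_shat[bi] <- sigma_hat; b_estar[bi] <- e_star
        b_Ao[bi] <- mean(e_o)
        next
      }

      k <- k + 1L
      sigma_blk <- max(model$sigma0 * model$sigma_decay^(k - 1L),
                       model$sigma_floor)
      b_strue[bi] <- sigma_blk

      if (session == "competition") {
        opp_i <- opp_i + 1L
        comp_j <- comp_j + 1L
        sigma_hat <- if (proto$schedule$sigma_mode == "frozen_baseline") {
          sigma_base40
        } else {
          estimate_sigma(history, 40)
        }
        if (!is.finite(sigma_hat) || sigma_hat <= 0) {
          stop("degenerate opponent: estimated sigma is 0.", call. = FALSE)
        }
        alpha <- proto$schedule$alpha[opp_i]
        e_star_opp <- optimal_aim(sigma_hat, gf)
        # the opponent's reaches are drawn first: the subject sees and
        # responds to the opponent's realised behaviour relative to its own
        # observed baseline mean, not to the hidden programmed aim
        e_o <- round(sample_opponent_endpoint(alpha, e_star_opp, sigma_hat,
                                              n_tr), 4)
        x <- mean(e_o) - ref
        jit <- stats::rnorm(1, 0, model$response_noise)
        aims <- vapply(seq_len(n_tr), function(t) {
          subject_block_aim(model, ref - model$baseline_bias, x, comp_j, t,
                            jit)
        }, numeric(1))
        e_s <- round(stats::rnorm(n_tr, aims, sigma_blk), 4)
        sc_s <- gain(e_s, gf); sc_o <- gain(e_o, gf)
        # strict alternation, subject first
        idx_s <- ti + 2L * seq_len(n_tr) - 1L
        idx_o <- ti + 2L * seq_len(n_tr)
        ti <- ti + 2L * n_tr
        t_sess[c(idx_s, idx_o)] <- session
        t_blk[c(idx_s, idx_o)] <- j
        t_tr[idx_s] <- seq_len(n_tr); t_tr[idx_o] <- seq_len(n_tr)
        t_role[idx_s] <- "subject"; t_role[idx_o] <- "opponent"
        t_ep[idx_s] <- e_s; t_ep[idx_o] <- e_o
        t_sc[idx_s] <- sc_s; t_sc[idx_o] <- sc_o
        history <- c(history, e_s)
        st <- sum(sc_s); ot <- sum(sc_o)
        b_alpha[bi] <- alpha; b_shat[bi] <- sigma_hat
        b_estar[bi] <- e_star_opp
        b_A[bi] <- mean(e_s); b_Ao[bi] <- mean(e_o)
        b_st[bi] <- st; b_ot[bi] <- ot
        b_win[bi] <- if (st > ot) "subject" else if (ot > st) "opponent"
                     else "tie"
        next
      }

      # individual-style reaching (baseline/individual/washout/observation/
      # threshold): aim at this block's optimum plus the subject's bias
      e_star_blk <- optimal_aim(sigma_blk, gf)
      jit <- stats::rnorm(1, 0, model$response_noise)
      aim <- subject_block_aim(model, e_star_blk, NULL, 1L, 1L, jit)
      e_s <- round(stats::rnorm(n_tr, aim, sigma_blk), 4)
      sc_s <- gain(e_s, gf)
      b_estar[bi] <- e_star_blk

      if (session == "observation") {
        # the risk-averse opponent is shown, alternating as in competition,
        # but the subject's goal (and model) is the individual task
        opp_i <- opp_i + 1L
        sigma_hat <- estimate_sigma(history, 40)
        alpha <- proto$schedule$alpha[opp_i]
        e_star_obs <- optimal_aim(sigma_hat, gf)
        e_o <- round(sample_opponent_endpoint(alpha, e_star_obs, sigma_hat,
                                              n_tr), 4)
        sc_o <- gain(e_o, gf)
        idx_s <- ti + 2L * seq_len(n_tr) - 1L
        idx_o <- ti + 2L * seq_len(n_tr)
        ti <- ti + 2L * n_tr
        t_sess[c(idx_s, idx_o)] <- session
        t_blk[c(idx_s, idx_o)] <- j
        t_tr[idx_s] <- seq_len(n_tr); t_tr[idx_o] <- seq_len(n_tr)
        t_role[idx_s] <- "subject"; t_role[idx_o] <- "opponent"
        t_ep[idx_s] <- e_s; t_ep[idx_o] <- e_o
        t_sc[idx_s] <- sc_s; t_sc[idx_o] <- sc_o
        b_alpha[bi] <- alpha; b_shat[bi] <- sigma_hat
        b_estar[bi] <- e_star_obs
        b_Ao[bi] <- mean(e_o); b_ot[bi] <- sum(sc_o)
      } else {
        if (session == "threshold") {
          opp_i <- opp_i + 1L
          sigma_hat <- estimate_sigma(history, 40)
          alpha <- proto$schedule$alpha[opp_i]
          e_star_thr <- optimal_aim(sigma_hat, gf)
          b_thr[bi] <- threshold_for_block(alpha, e_star_thr, sigma_hat, gf,
                                           n_tr)
          b_alpha[bi] <- alpha; b_shat[bi] <- sigma_hat
          b_estar[bi] <- e_star_thr
        }
        idx <- ti + seq_len(n_tr); ti <- ti + n_tr
        t_sess[idx] <- session; t_blk[idx] <- j; t_tr[idx] <- seq_len(n_tr)
        t_role[idx] <- "subject"; t_ep[idx] <- e_s; t_sc[idx] <- sc_s
      }
      history <- c(history, e_s)
      st <- sum(sc_s)
      b_A[bi] <- mean(e_s); b_st[bi] <- st
      if (session == "threshold") {
        b_win[bi] <- if (st > b_thr[bi]) "subject" else "opponent"
      }

      if (session == "baseline") {
        n_base <- n_base + n_tr
        if (j == n_blocks) {
          # the subject's observed baseline mean anchors its competitive
          # response; the frozen opponent sigma is the last 40 baseline trials
          ref <- mean(utils::tail(history, n_base))
          sigma_base40 <- estimate_sigma(history, 40)
        }
      }
    }
  }
  trials <- tibble::tibble(
    subject_id = subject_id, group = proto$name, session = t_sess,
    block = t_blk, trial = t_tr, role = t_role, endpoint_cm = t_ep,
    score = t_sc, mistrial = t_ep > gf$boundary | t_ep <= gf$dead_zone)
  blocks <- tibble::tibble(
    subject_id = subject_id, group = proto$name, session = b_sess,
    block = b_blk, alpha = b_alpha, sigma_true = b_strue, sigma_hat = b_shat,
    E_star = b_estar, A = b_A, A_o = b_Ao, subject_total = b_st,
    opponent_total = b_ot, threshold = b_thr, winner = b_win)
  list(trials = trials, blocks = blocks)
}

#' Run a protocol for a cohort of synthetic subjects
#'
#' Simulates `n_subjects` independent subjects through `proto`, each with a
#' baseline bias drawn from `N(baseline_bias, baseline_bias_sd^2)`. Each
#' subject gets a deterministic child seed derived from `seed`, so enlarging
#' the cohort never perturbs earlier subjects and the output is
#' byte-reproducible.
#'
#' @param proto A [protocol()] (or preset name).
#' @param n_subjects Number of subjects (0 gives an empty, well-formed table).
#' @param model A [subject_model()].
#' @param seed Integer root seed.
#' @param gf A [gain_function()].
#' @param subject_prefix Prefix for subject identifiers (default `"s"`).
#' @return A list with `trials` (one row per reach) and `blocks` (one row per
#'   block with aims, totals, the opponent's `sigma_hat`/`E_star`, and the
#'   winner).
#' @examples
#' run <- run_experiment(protocol("exp1b"), n_subjects = 2, seed = 1)
#' dplyr::count(run$trials, session, role)
#' @export
run_experiment <- function(proto, n_subjects, model = subject_model(),
                           seed = 1L, gf = gain_function(),
                           subject_prefix = "s") {
  if (is.character(proto)) proto <- protocol(proto)
  stopifnot(inherits(proto, "mc_protocol"), inherits(model, "subject_model"),
            n_subjects >= 0)
  out_t <- list(); out_b <- list()
  for (i in seq_len(n_subjects)) {
    set.seed(child_seed(seed, i))
    model_i <- model
    model_i$baseline_bias <-
      stats::rnorm(1, model$baseline_bias, model$baseline_bias_sd)
    res <- simulate_subject(proto, model_i, sprintf("%s%02d", subject_prefix, i),
                            gf)
    out_t[[i]] <- res$trials; out_b[[i]] <- res$blocks
  }
  list(trials = dplyr::bind_rows(c(list(trial_cols()), out_t)),
       blocks = dplyr::bind_rows(c(list(block_cols()), out_b)))
}

child_seed <- function(seed, i) {
  (as.double(seed) %% 2147483647 + 104729 * i) %% 2147483647
}

#' Generate a synthetic trial table
#'
#' Convenience wrapper around [run_experiment()] that returns only the trial
#' table (the per-block summaries can be recomputed with
#' [summarize_blocks()]).
#'
#' @inheritParams run_experiment
#' @return A tibble of trial records.
#' @examples
#' trials <- generate_cohort("exp1a", n_subjects = 1, seed = 42)
#' head(trials)
#' @export
generate_cohort <- function(proto, n_subjects, model = subject_model(),
                            seed = 1L, gf = gain_function(),
                            subject_prefix = "s") {
  run_experiment(proto, n_subjects, model, seed, gf, subject_prefix)$trials
}

#' Per-block summaries from a trial table
#'
#' Recomputes block-level aim points, totals and the winner from the trial
#' records alone (no generative state needed).
#'
#' @param trials A trial table.
#' @return A tibble with one row per subject x session x block.
#' @export
summarize_blocks <- function(trials) {
  trials |>
    dplyr::group_by(.data$subject_id, .data$group, .data$session,
                    .data$block) |>
    dplyr::summarise(
      A = mean(.data$endpoint_cm[.data$role == "subject"]),
      A_o = mean(.data$endpoint_cm[.data$role == "opponent"]),
      subject_total = sum(.data$score[.data$role == "subject"]),
      opponent_total = sum(.data$score[.data$role == "opponent"]),
      .groups = "drop") |>
    dplyr::mutate(winner = dplyr::case_when(
      is.na(.data$A_o) ~ NA_character_,
      .data$subject_total > .data$opponent_total ~ "subject",
      .data$subject_total < .data$opponent_total ~ "opponent",
      TRUE ~ "tie"))
}
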