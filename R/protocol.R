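#' Experiment protocol
#'
#' A protocol is the ordered list of sessions a subject performs, each a run
#' of 10-trial blocks, together with the opponent schedule for any
#' competitive (or observation/threshold) session. Presets reproduce the five
#' study designs:
#'
#' | preset | sessions (blocks) |
#' |---|---|
#' | `exp1a` | baseline (5), competition (12, risk-neutral), washout (5) |
#' | `exp1b` | baseline (5), competition (12, turning risk-averse), washout (5) |
#' | `exp1c` | baseline (5), individual (17), competition (4) |
#' | `exp2`  | baseline (5), presentation (1), competition (12), washout (5) |
#' | `exp4`  | baseline (5), competition (12, highly risk-averse, frozen sigma), washout (5) |
#' | `exp5_observation` | baseline (5), observation (12), washout (5) |
#' | `exp5_threshold`   | baseline (5), threshold (12), washout (5) |
#'
#' The presentation session is a single pseudo-block of 10 opponent-only
#' trials shown before competition.
#'
#' @param preset Preset name, or `NULL` to build a custom protocol from
#'   `sessions` and `schedule`.
#' @param sessions Data frame with columns `session` (one of `baseline`,
#'   `individual`, `competition`, `washout`, `observation`, `threshold`,
#'   `presentation`) and `n_blocks`.
#' @param schedule An [opponent_schedule()]; required when the protocol has a
#'   competition, observation or threshold session. Its length must equal the
#'   number of blocks of that session.
#' @param n_trials Trials per block per role (default 10).
#' @return An object of class `mc_protocol`.
#' @examples
#' protocol("exp1b")
#' @export
protocol <- function(preset = NULL, sessions = NULL, schedule = NULL,
                     n_trials = 10) {
  session_levels <- c("baseline", "individual", "competition", "washout",
                      "observation", "threshold", "presentation")
  if (!is.null(preset)) {
    tbl <- function(...) {
      m <- matrix(c(...), ncol = 2, byrow = TRUE)
      data.frame(session = m[, 1], n_blocks = as.integer(m[, 2]))
    }
    defs <- list(
      exp1a = tbl("baseline", 5, "competition", 12, "washout", 5),
      exp1b = tbl("baseline", 5, "competition", 12, "washout", 5),
      exp1c = tbl("baseline", 5, "individual", 17, "competition", 4),
      exp2  = tbl("baseline", 5, "presentation", 1, "competition", 12,
                  "washout", 5),
      exp4  = tbl("baseline", 5, "competition", 12, "washout", 5),
      exp5_observation = tbl("baseline", 5, "observation", 12, "washout", 5),
      exp5_threshold   = tbl("baseline", 5, "threshold", 12, "washout", 5)
    )
    if (!preset %in% names(defs)) {
      stop("unknown protocol preset: ", preset, call. = FALSE)
    }
    sessions <- sessions %||% defs[[preset]]
    schedule <- schedule %||% opponent_schedule(preset)
  }
  if (is.null(sessions) || !all(c("session", "n_blocks") %in% names(sessions))) {
    stop("`sessions` must have columns session and n_blocks.", call. = FALSE)
  }
  if (!all(sessions$session %in% session_levels)) {
    stop("unknown session type(s): ",
         paste(setdiff(sessions$session, session_levels), collapse = ", "),
         call. = FALSE)
  }
  opp_sessions <- c("competition", "observation", "threshold")
  n_opp <- sum(sessions$n_blocks[sessions$session %in% opp_sessions])
  if (n_opp > 0) {
    if (is.null(schedule)) {
      stop("protocol has opponent-facing blocks but no `schedule`.",
           call. = FALSE)
    }
    if (length(schedule$alpha) != n_opp) {
      stop(sprintf(
        "schedule length (%d) must match opponent-facing blocks (%d).",
        length(schedule$alpha), n_opp), call. = FALSE)
    }
  }
  structure(list(name = preset %||% "custom",
                 sessions = tibble::as_tibble(sessions),
                 schedule = schedule, n_trials = as.integer(n_trials)),
            class = "mc_protocol")
}

#' @export
print.mc_protocol <- function(x, ...) {
  cat(sprintf("<protocol> %s: %s (%d trials/block)\n", x$name,
              paste(sprintf("%s(%d)", x$sessions$session, x$sessions$n_blocks),
                    collapse = " + "),
              x$n_trials))
  if (!is.null(x$schedule)) print(x$schedule)
  invisible(x)
}
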