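#' Monte-Carlo chance of winning a block
#'
#' Simulates `n_reps` blocks: in each, the subject reaches `n_trials` times
#' from `N(aim_s, sigma_s^2)` and the opponent from `N(aim_o, sigma_o^2)`,
#' both scored by the gain function, and the higher 10-trial total wins. Ties
#' earn half credit by default (`tie = "half"`), which preserves the symmetry
#' `P(A beats B) + P(B beats A) = 1`; `tie = "strict"` counts only outright
#' wins.
#'
#' @param aim_s,sigma_s Subject aim (cm) and endpoint SD (cm, > 0).
#' @param aim_o,sigma_o Opponent aim and endpoint SD.
#' @param gf A [gain_function()].
#' @param n_trials Trials per role per block (default 10).
#' @param n_reps Simulated blocks (default 10000).
#' @param tie `"half"` or `"strict"`.
#' @param seed Optional integer seed.
#' @return Estimated win probability in `[0, 1]`.
#' @examples
#' chance_of_winning(27.1, 1, 27.1, 1, n_reps = 2000)  # ~0.5 by symmetry
#' @export
chance_of_winning <- function(aim_s, sigma_s, aim_o, sigma_o,
                              gf = gain_function(), n_trials = 10,
                              n_reps = 10000, tie = c("half", "strict"),
                              seed = NULL) {
  tie <- match.arg(tie)
  if (!all(is.finite(c(aim_s, sigma_s, aim_o, sigma_o))) ||
      sigma_s <= 0 || sigma_o <= 0 || n_trials < 1 || n_reps < 1) {
    stop("invalid parameters: sigmas must be > 0, counts >= 1.",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  tot_s <- colSums(matrix(
    gain(stats::rnorm(n_trials * n_reps, aim_s, sigma_s), gf), n_trials))
  tot_o <- colSums(matrix(
    gain(stats::rnorm(n_trials * n_reps, aim_o, sigma_o), gf), n_trials))
  wins <- mean(tot_s > tot_o)
  if (tie == "half") wins + 0.5 * mean(tot_s == tot_o) else wins
}

#' Win-chance map over the relative-aim plane
#'
#' For each observed block context (opponent aim and SD, subject SD, and the
#' subject's individual-task aim `A_i`), evaluates the chance of winning over
#' a grid of candidate subject aims, places each evaluation at
#' `(x, y) = (opp_aim - A_i, aim - A_i)`, and averages within half-open
#' square bins of width `bin` (the map shading of the non-linearity figure).
#'
#' @param contexts Data frame with columns `A_i`, `opp_aim`, `opp_sigma`,
#'   `subj_sigma` (cm), one row per block.
#' @param aim_range Range of subject aims relative to `A_i`, in cm (default
#'   `c(-4, 2)`).
#' @param bin Bin width in cm (default 0.25).
#' @param gf A [gain_function()].
#' @param n_trials Trials per role per block (default 10).
#' @param n_reps Monte-Carlo repetitions per aim (default 10000).
#' @param tie Tie rule, see [chance_of_winning()].
#' @param seed Optional integer seed.
#' @return A tibble `x_bin`, `y_bin` (bin centres, cm), `chance`, `n_points`.
#' @export
winning_grid <- function(contexts, aim_range = c(-4, 2), bin = 0.25,
                         gf = gain_function(), n_trials = 10, n_reps = 10000,
                         tie = c("half", "strict"), seed = NULL) {
  tie <- match.arg(tie)
  req <- c("A_i", "opp_aim", "opp_sigma", "subj_sigma")
  if (nrow(contexts) == 0) stop("`contexts` is empty.", call. = FALSE)
  if (!all(req %in% names(contexts))) {
    stop("`contexts` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  rel_aims <- seq(aim_range[1], aim_range[2], by = bin)
  if (length(rel_aims) == 0) stop("empty aim grid.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pts <- purrr::map_dfr(seq_len(nrow(contexts)), function(i) {
    ctx <- contexts[i, ]
    chance <- vapply(rel_aims, function(ra) {
      chance_of_winning(ctx$A_i + ra, ctx$subj_sigma, ctx$opp_aim,
                        ctx$opp_sigma, gf, n_trials, n_reps, tie)
    }, numeric(1))
    tibble::tibble(x = ctx$opp_aim - ctx$A_i, y = rel_aims, chance = chance)
  })
  # half-open bins [lo, lo + bin); centre reported
  pts |>
    dplyr::mutate(x_bin = floor(.data$x / bin) * bin + bin / 2,
                  y_bin = floor(.data$y / bin) * bin + bin / 2) |>
    dplyr::group_by(.data$x_bin, .data$y_bin) |>
    dplyr::summarise(chance = mean(.data$chance), n_points = dplyr::n(),
                     .groups = "drop")
}
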