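#' Plot the gain function and expected-gain curves
#'
#' Shows the score-versus-endpoint mapping together with the expected gain
#' as a function of the aim point for one or more noise levels, each with its
#' optimal aim point marked.
#'
#' @param gf A [gain_function()].
#' @param sigmas Motor SDs in cm to overlay (default `c(0.5, 1, 1.5, 2)`).
#' @return A ggplot object.
#' @export
plot_gain_model <- function(gf = gain_function(), sigmas = c(0.5, 1, 1.5, 2)) {
  e <- seq(gf$dead_zone - 2, gf$boundary + 3, length.out = 400)
  gdat <- tibble::tibble(e = e, value = gain(e, gf), curve = "gain G(e)")
  edat <- purrr::map_dfr(sigmas, function(s) {
    tibble::tibble(e = e, value = expected_gain(e, s, gf),
                   curve = sprintf("EG, sigma = %.2g cm", s))
  })
  stars <- tibble::tibble(
    e = optimal_aim(sigmas, gf),
    curve = sprintf("EG, sigma = %.2g cm", sigmas))
  stars$value <- purrr::map2_dbl(stars$e, sigmas,
                                 function(E, s) expected_gain(E, s, gf))
  ggplot2::ggplot(dplyr::bind_rows(gdat, edat),
                  ggplot2::aes(x = .data$e, y = .data$value,
                               colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = stars, shape = 8, size = 2.5,
                        show.legend = FALSE) +
    ggplot2::labs(x = "endpoint / aim point (cm)", y = "points",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-block aim points across a session
#'
#' Mean subject (and, where present, opponent) endpoint per competitive
#' block, averaged across subjects with a standard-error ribbon — the
#' aim-point trajectory view.
#'
#' @param blocks A block summary table ([run_experiment()]`$blocks` or
#'   [summarize_blocks()]).
#' @param sessions Sessions to include (default competition only).
#' @return A ggplot object.
#' @export
plot_aim_series <- function(blocks, sessions = "competition") {
  dat <- blocks |>
    dplyr::filter(.data$session %in% sessions) |>
    tidyr::pivot_longer(dplyr::all_of(c("A", "A_o")), names_to = "who",
                        values_to = "aim") |>
    dplyr::filter(is.finite(.data$aim)) |>
    dplyr::mutate(who = dplyr::recode(.data$who, A = "subject",
                                      A_o = "opponent")) |>
    dplyr::group_by(.data$session, .data$block, .data$who) |>
    dplyr::summarise(mean = mean(.data$aim),
                     se = stats::sd(.data$aim) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$block, y = .data$mean,
                                    colour = .data$who, fill = .data$who)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = scales_breaks_int) +
    ggplot2::labs(x = "block", y = "mean endpoint (cm)", colour = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

scales_breaks_int <- function(lims) {
  seq(ceiling(lims[1]), floor(lims[2]), by = max(1, round(diff(lims) / 8)))
}

#' Plot the relative-aim scatter with half-plane regressions
#'
#' The subject's relative aim against the opponent's relative aim, with
#' separate least-squares lines left and right of the split — the
#' non-linearity view. Optionally shaded by a win-chance map.
#'
#' @param points Output of [relative_aims()].
#' @param split_at Split point on `x` (default 0).
#' @param grid Optional [winning_grid()] output to draw underneath.
#' @return A ggplot object.
#' @export
plot_relative_aims <- function(points, split_at = 0, grid = NULL) {
  sl <- split_slopes(points, split_at)
  seg <- sl |>
    dplyr::mutate(
      x0 = ifelse(.data$side == "left", min(points$x), split_at),
      x1 = ifelse(.data$side == "left", split_at, max(points$x)),
      y0 = .data$intercept + .data$slope * .data$x0,
      y1 = .data$intercept + .data$slope * .data$x1)
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(grid)) {
    p <- p + ggplot2::geom_tile(
      data = grid, ggplot2::aes(x = .data$x_bin, y = .data$y_bin,
                                fill = .data$chance),
      inherit.aes = FALSE, alpha = 0.8) +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1))
  }
  p +
    ggplot2::geom_point(ggplot2::aes(shape = .data$group), alpha = 0.7) +
    ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y0,
                               yend = .data$y1, colour = .data$side),
      linewidth = 1, inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = split_at, linetype = 3) +
    ggplot2::labs(x = "opponent relative aim A_o - A_i (cm)",
                  y = "subject relative aim A_c - A_i (cm)",
                  colour = "half", fill = "chance of winning",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Histograms of bootstrapped half-plane slopes
#'
#' @param object A `slope_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slope_test <- function(object, ...) {
  dat <- tibble::tibble(
    slope = c(object$boot_left, object$boot_right),
    side = rep(c("left", "right"), each = object$n_boot))
  means <- tibble::tibble(side = c("left", "right"),
                          m = c(mean(object$boot_left),
                                mean(object$boot_right)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$slope, fill = .data$side)) +
    ggplot2::geom_histogram(bins = 80, alpha = 0.6,
                            position = "identity") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$m,
                                     colour = .data$side),
                        linewidth = 0.8) +
    ggplot2::labs(
      x = "bootstrapped regression slope", y = "count",
      subtitle = sprintf("permutation p = %.4g (%d resamples)",
                         object$p_perm, object$n_boot)) +
    ggplot2::theme_minimal()
}

#' Plot risk-sensitivity by block
#'
#' Risk-sensitivity (mean endpoint minus optimal aim) for the baseline and
#' each competitive block, averaged across subjects with a standard-error
#' ribbon.
#'
#' @param trials A trial table.
#' @param gf A [gain_function()].
#' @return A ggplot object.
#' @export
plot_risk_sensitivity <- function(trials, gf = gain_function()) {
  base <- cohort_risk_sensitivity(trials, "baseline", gf = gf) |>
    dplyr::mutate(block = 0L)
  per_block <- purrr::map_dfr(
    sort(unique(trials$block[trials$session == "competition"])),
    function(b) {
      cohort_risk_sensitivity(trials, "competition", blocks = b, gf = gf) |>
        dplyr::mutate(block = b)
    })
  dat <- dplyr::bind_rows(base, per_block) |>
    dplyr::group_by(.data$group, .data$block) |>
    dplyr::summarise(mean = mean(.data$risk_sensitivity),
                     se = stats::sd(.data$risk_sensitivity) /
                       sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$block, y = .data$mean,
                                    colour = .data$group,
                                    fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(
      breaks = scales_breaks_int,
      labels = function(b) ifelse(b == 0, "BL", b)) +
    ggplot2::labs(x = "block (BL = baseline)",
                  y = "risk-sensitivity (cm)", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
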