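#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a slope test
#'
#' One row per half-plane: point estimate, bootstrap 95% percentile CI.
#'
#' @param x A `slope_test` from [bootstrap_permutation_slopes()].
#' @param ... Unused.
#' @return A tibble with columns `side`, `n`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.slope_test <- function(x, ...) {
  tibble::tibble(side = c("left", "right"),
                 n = c(x$n_left, x$n_right),
                 estimate = c(x$slope_left, x$slope_right),
                 conf.low = c(x$ci_left[1], x$ci_right[1]),
                 conf.high = c(x$ci_left[2], x$ci_right[2]))
}

#' Glance at a slope test
#'
#' @param x A `slope_test`.
#' @param ... Unused.
#' @return A one-row tibble: `p_perm`, `n_boot`, `n_redrawn`, `tie`,
#'   `split_at`, and the slope difference `delta_slope`.
#' @export
glance.slope_test <- function(x, ...) {
  tibble::tibble(p_perm = x$p_perm, n_boot = x$n_boot,
                 n_redrawn = x$n_redrawn, tie = x$tie, split_at = x$split_at,
                 delta_slope = x$slope_right - x$slope_left)
}
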