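# Independent brute-force oracles, deliberately kept apart from the package's
# closed-form/optimizer code paths.

# dense trapezoid quadrature of gain * normal density
eg_trapezoid <- function(aim, sigma, gf, step = 1e-4) {
  lo <- max(gf$dead_zone, aim - 8 * sigma)
  hi <- min(gf$boundary, aim + 8 * sigma)
  if (hi <= lo) return(0)
  e <- seq(lo, hi, by = step)
  if (e[length(e)] < hi) e <- c(e, hi)
  f <- gain(e, gf) * stats::dnorm(e, aim, sigma)
  sum(diff(e) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}

# exhaustive grid search for the expected-gain maximiser
estar_grid_search <- function(sigma, gf, by = 1e-3) {
  grid <- seq(gf$dead_zone + by, gf$boundary, by = by)
  grid[which.max(expected_gain(grid, sigma, gf))]
}

# direct two-pass sample SD (n - 1 denominator)
sd_two_pass <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# synthetic two-slope point cloud in the relative-aim plane
two_slope_points <- function(n = 88, slope_neg = 0.2, slope_pos = 0.6,
                             noise = 0.3, x_range = c(-3, 1)) {
  x <- stats::runif(n, x_range[1], x_range[2])
  y <- ifelse(x >= 0, slope_pos * x, slope_neg * x) +
    stats::rnorm(n, 0, noise)
  tibble::tibble(x = x, y = y)
}
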