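# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# noise-free concentration series from explicit exponentials (not hga_at)
make_conversion_series <- function(hga0, hgb0, k, l, grid) {
  A <- k / (l - k) * hgb0
  hga <- A * exp(-k * grid) + (hga0 - A) * exp(-l * grid)
  hgb <- hgb0 * exp(-k * grid)
  tibble::tibble(
    time_h = rep(grid, 2),
    analyte = rep(c("HGA", "HGB"), each = length(grid)),
    value = c(hga, hgb)
  )
}

# O(n^2) brute-force tie-corrected Kendall tau-b
tau_b_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) { tie_x <- tie_x + 1; tie_y <- tie_y + 1 }
      else if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if (sign(dx) == sign(dy)) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# classical Spearman formula (valid only without ties)
spearman_no_ties <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# dense grid-search maximiser of the HGA curve, independent of the closed
# form for the peak time
grid_peak <- function(params, t_max = 200, res = 1e-4) {
  coarse <- seq(0, t_max, by = 0.05)
  v <- rumentox::hga_at(params, coarse)
  i <- which.max(v)
  lo <- max(coarse[i] - 0.05, 0); hi <- min(coarse[i] + 0.05, t_max)
  fine <- seq(lo, hi, by = res)
  fine[which.max(rumentox::hga_at(params, fine))]
}

# standard error of the sample SD of n lognormal draws with the given
# mean and SD, from the delta method with the lognormal's exact kurtosis
lognormal_sd_se <- function(mean, sd, n) {
  omega <- 1 + (sd / mean)^2          # e^(sigma^2)
  kurt <- omega^4 + 2 * omega^3 + 3 * omega^2 - 3
  sd * sqrt((kurt - 1) / (4 * n))
}

# quick tidy-extraction helpers
est_of <- function(fit, term) {
  td <- rumentox::tidy(fit)
  td$estimate[td$term == term]
}
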