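test_that("pressure-to-volume follows the ideal gas relation", {
  expect_equal(pressure_to_volume(0), 0)
  # hand calculation: 1 psi, 106 mL headspace, 39 C, STP reporting
  n <- 6894.76 * 106e-6 / (8.314 * (39 + 273.15))
  expect_equal(pressure_to_volume(1), n * 22414, tolerance = 1e-12)
  expect_equal(pressure_to_volume(1), 6.31, tolerance = 1e-3)

  # linear and homogeneous in pressure and headspace
  expect_equal(pressure_to_volume(2), 2 * pressure_to_volume(1))
  expect_equal(pressure_to_volume(1, headspace = 212),
               2 * pressure_to_volume(1, headspace = 106))
  # incubation reference: volume at 39 C and 101325 Pa
  expect_equal(pressure_to_volume(1, reference = "incubation"),
               n * 8.314 * (39 + 273.15) / 101325 * 1e6,
               tolerance = 1e-12)
  expect_error(pressure_to_volume(-1), "Negative")
})

test_that("blank correction subtracts the pointwise mean blank", {
  tt <- c(0, 1, 2)
  test <- tibble::tibble(fermenter = "T1", time_h = tt,
                         cum_pressure_psi = c(10, 10, 10))
  blanks <- dplyr::bind_rows(
    tibble::tibble(fermenter = "B1", time_h = tt, cum_pressure_psi = 2),
    tibble::tibble(fermenter = "B2", time_h = tt, cum_pressure_psi = 4)
  )
  out <- blank_correct(test, blanks)
  expect_equal(out$cum_pressure_psi, rep(7, 3))

  # zero blank is the identity; test == mean blank gives all zeros
  zero <- tibble::tibble(fermenter = "B", time_h = tt, cum_pressure_psi = 0)
  expect_equal(blank_correct(test, zero)$cum_pressure_psi, rep(10, 3))
  expect_equal(blank_correct(test, test)$cum_pressure_psi, rep(0, 3))
})

test_that("blank correction interpolates misaligned grids and flags gaps", {
  test <- tibble::tibble(fermenter = "T", time_h = c(0, 1, 2),
                         cum_pressure_psi = c(3, 5, 7))
  blanks <- tibble::tibble(fermenter = "B", time_h = c(0, 2),
                           cum_pressure_psi = c(0, 2))   # linear in t
  out <- blank_correct(test, blanks)
  expect_equal(out$cum_pressure_psi, c(3, 4, 5))

  late <- tibble::tibble(fermenter = "B", time_h = c(10, 12),
                         cum_pressure_psi = c(0, 0))
  expect_error(blank_correct(test, late), "overlap")
  expect_error(blank_correct(test, blanks[0, ]), "empty")
})

test_that("downsampling keeps the last observation per grid point", {
  tt <- seq(0, 48, by = 1 / 12)     # native 5-min interval
  curve <- tibble::tibble(fermenter = "F", time_h = tt,
                          cum_pressure_psi = seq_along(tt))
  thin <- downsample_curve(curve, 0.5)
  expect_equal(nrow(thin), 97)       # 48 / 0.5 + 1
  expect_equal(thin$time_h[1], 0)
  expect_true(all(diff(thin$cum_pressure_psi) > 0))  # monotone preserved

  span <- downsample_curve(curve, 48)
  expect_equal(nrow(span), 2)

  expect_error(downsample_curve(curve, 1 / 24), "coarser")
  expect_error(downsample_curve(curve[0, ], 0.5), "Empty")
})

test_that("the (a, b, c) parameterization satisfies its defining constraints", {
  sh <- abc_to_shape(18.6, 8.5)
  expect_equal(unname(sh["s"]), 7.556, tolerance = 1e-3)  # frozen
  expect_equal(unname(sh["m"]), 19.31, tolerance = 1e-3)

  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 50, 500); b <- runif(1, 2, 60); c <- runif(1, 1, 40)
    g <- gompertz_params(a, b, c)
    expect_lt(abs(gompertz_value(g, b) - a / 3) / a, 1e-9)
    expect_lt(abs(gompertz_value(g, b + c) - 0.7 * a) / a, 1e-9)
    # inflection property of the Gompertz curve
    expect_equal(gompertz_value(g, g$m), a / exp(1), tolerance = 1e-9)
  }
  expect_error(abc_to_shape(-1, 5), "positive")
})

test_that("gompertz_value is increasing with the declared asymptote", {
  g <- gompertz_params(200, 18.6, 8.5)
  expect_equal(gompertz_value(g, 27.1), 140, tolerance = 1e-6)
  expect_equal(gompertz_value(g, 18.6), 200 / 3, tolerance = 1e-9)
  tt <- seq(0, 96, by = 0.5)
  expect_true(all(diff(gompertz_value(g, tt)) > 0))
  expect_equal(gompertz_value(g, 1e5), 200, tolerance = 1e-9)
})

test_that("gompertz refits recover known parameters on clean data", {
  for (row in list(c(a = 200, b = 18.6, c = 8.5),
                   c(a = 453, b = 43.5, c = 32.1))) {
    horizon <- if (row["b"] > 30) 96 else 48
    tt <- seq(0, horizon, by = 0.5)
    g <- gompertz_params(row["a"], row["b"], row["c"])
    d <- tibble::tibble(time_h = tt, vol_ml_per_g = gompertz_value(g, tt))
    fit <- fit_gompertz(d)
    expect_true(fit$converged)
    td <- tidy(fit)
    expect_equal(setNames(td$estimate, td$term), row, tolerance = 1e-4)
    expect_gt(glance(fit)$r2, 0.9999)
  }
})

test_that("noisy gompertz refits keep R2 > 0.99 and cover the truth", {
  truth <- c(a = 272, b = 17.5, c = 10.7)
  tt <- seq(0, 48, by = 0.5)
  g <- gompertz_params(truth["a"], truth["b"], truth["c"])
  clean <- gompertz_value(g, tt)
  covered <- matrix(NA, 200, 3, dimnames = list(NULL, names(truth)))
  r2 <- numeric(200)
  set.seed(314)
  for (i in 1:200) {
    d <- tibble::tibble(time_h = tt,
                        vol_ml_per_g = clean * rnorm(length(tt), 1, 0.02))
    # relative (multiplicative) noise calls for proportional weighting;
    # unweighted OLS undercovers the asymptote under this error model
    fit <- fit_gompertz(d, n_starts = 2, weights = "proportional")
    td <- tidy(fit)
    covered[i, ] <- td$conf.low <= truth & truth <= td$conf.high
    r2[i] <- glance(fit)$r2
  }
  expect_true(all(colMeans(covered) >= 0.90))
  expect_true(all(r2 > 0.99))
})

test_that("flat or short gas curves are flagged, not fitted", {
  flat <- tibble::tibble(time_h = seq(0, 48, 4), vol_ml_per_g = 0)
  expect_false(fit_gompertz(flat)$converged)
  expect_match(fit_gompertz(flat)$message, "degenerate|flat")

  short <- tibble::tibble(time_h = c(0, 12, 24), vol_ml_per_g = c(0, 50, 100))
  expect_false(fit_gompertz(short)$converged)
})
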