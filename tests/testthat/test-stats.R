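make_metab <- function(analyte, values, time_h = 24, run = 1) {
  tibble::tibble(run = run, fermenter = paste0("F", seq_along(values)),
                 variant = "PCM", time_h = time_h,
                 analyte = analyte, value = values)
}

test_that("NH3 is reported as test minus mean blank, sign preserved", {
  test <- make_metab("NH3", 5.2, time_h = 0)
  blanks <- make_metab("NH3", 7.0, time_h = 0)
  expect_equal(nh3_difference(test, blanks)$value, -1.8)

  # two blanks average before subtraction
  test2 <- make_metab("NH3", 10, time_h = 0)
  blanks2 <- make_metab("NH3", c(6, 8), time_h = 0)
  expect_equal(nh3_difference(test2, blanks2)$value, 3)

  # identical test and blanks cancel
  expect_equal(nh3_difference(test, test)$value, 0)

  # non-NH3 analytes pass through untouched
  mixed <- dplyr::bind_rows(test, make_metab("acetic", 22, time_h = 0))
  out <- nh3_difference(mixed, blanks)
  expect_equal(out$value[out$analyte == "acetic"], 22)

  late <- make_metab("NH3", 5, time_h = 48)
  expect_error(nh3_difference(late, blanks), "time point")
})

test_that("C2:C3 is computed per fermenter, zero propionate flagged", {
  d <- dplyr::bind_rows(make_metab("acetic", c(10, 0, 22)),
                        make_metab("propionic", c(5, 2, 4.3)))
  out <- suppressWarnings(c2_c3_ratio(d))
  ratios <- out$value[out$analyte == "C2:C3"]
  expect_equal(ratios, c(10 / 5, 0, 22 / 4.3))
  expect_equal(ratios[3], 5.12, tolerance = 1e-2)

  zero <- dplyr::bind_rows(make_metab("acetic", 10),
                           make_metab("propionic", 0))
  expect_warning(out0 <- c2_c3_ratio(zero), "Zero propionic")
  expect_true(is.na(out0$value[out0$analyte == "C2:C3"]))
})

test_that("self- and anti-correlations are exact for every method", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  d <- dplyr::bind_rows(make_metab("x", x), make_metab("y", -x),
                        make_metab("z", x))
  ct <- correlation_matrix(d, time_h = 24)
  for (m in c("pearson", "spearman", "kendall")) {
    r_xy <- ct$r[ct$method == m & ct$var1 == "x" & ct$var2 == "y"]
    r_xx <- ct$r[ct$method == m & ct$var1 == "x" & ct$var2 == "x"]
    r_xz <- ct$r[ct$method == m & ct$var1 == "x" & ct$var2 == "z"]
    expect_equal(r_xy, -1)
    expect_equal(r_xx, 1)
    expect_equal(r_xz, 1)
  }
})

test_that("Kendall matches the pairwise concordance definition", {
  # 5 concordant and 1 discordant of the 6 pairs
  d <- dplyr::bind_rows(make_metab("x", c(1, 2, 3, 4)),
                        make_metab("y", c(1, 2, 4, 3)))
  ct <- correlation_matrix(d, method = "kendall")
  expect_equal(ct$r[ct$var1 == "x" & ct$var2 == "y"], 2 / 3)

  # brute-force tau-b oracle on random tied data
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    x <- sample(1:6, n, replace = TRUE)       # heavy ties
    y <- x + sample(-2:2, n, replace = TRUE)
    d <- dplyr::bind_rows(make_metab("x", x), make_metab("y", y))
    ct <- correlation_matrix(d, method = "kendall")
    expect_equal(ct$r[ct$var1 == "x" & ct$var2 == "y"], tau_b_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Spearman equals rank-then-Pearson and the classical formula", {
  set.seed(6)
  x <- rnorm(12); y <- x + rnorm(12)          # no ties a.s.
  d <- dplyr::bind_rows(make_metab("x", x), make_metab("y", y))
  ct <- correlation_matrix(d, method = "spearman")
  r <- ct$r[ct$var1 == "x" & ct$var2 == "y"]
  expect_equal(r, spearman_no_ties(x, y), tolerance = 1e-12)
  expect_equal(r, cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("rank methods are invariant to monotone transforms, Pearson to affine", {
  set.seed(8)
  x <- rlnorm(15); y <- rnorm(15)
  d1 <- dplyr::bind_rows(make_metab("x", x), make_metab("y", y))
  d2 <- dplyr::bind_rows(make_metab("x", log(x)), make_metab("y", y^3 + 2))
  for (m in c("spearman", "kendall")) {
    r1 <- correlation_matrix(d1, method = m)
    r2 <- correlation_matrix(d2, method = m)
    expect_equal(r1$r, r2$r, tolerance = 1e-12)
  }
  d3 <- dplyr::bind_rows(make_metab("x", 3 * x - 7), make_metab("y", y / 2))
  p1 <- correlation_matrix(d1, method = "pearson")
  p3 <- correlation_matrix(d3, method = "pearson")
  expect_equal(p1$r, p3$r, tolerance = 1e-12)
})

test_that("constant columns and small n give missing correlations", {
  d <- dplyr::bind_rows(make_metab("x", c(1, 2, 3, 4)),
                        make_metab("y", rep(5, 4)))
  ct <- correlation_matrix(d, method = "pearson")
  expect_true(is.na(ct$r[ct$var1 == "x" & ct$var2 == "y"]))
  # diagonal of a constant column is still 1 by convention
  expect_equal(ct$r[ct$var1 == "y" & ct$var2 == "y"], 1)

  tiny <- dplyr::bind_rows(make_metab("x", c(1, 2)), make_metab("y", c(2, 1)))
  ct2 <- correlation_matrix(tiny, method = "pearson")
  expect_true(is.na(ct2$r[ct2$var1 == "x" & ct2$var2 == "y"]))
})

test_that("the wide table mirrors the long one with significance stars", {
  set.seed(9)
  x <- 1:8; y <- c(1, 2, 3, 4, 5, 6, 8, 7); z <- rnorm(8)
  d <- dplyr::bind_rows(make_metab("x", x), make_metab("y", y),
                        make_metab("z", z))
  ct <- correlation_matrix(d, method = "spearman")
  wide <- correlation_wide(ct)
  expect_setequal(names(wide), c("var1", "x", "y", "z"))
  cell <- wide[[match("y", names(wide))]][wide$var1 == "x"]
  expect_match(cell, "^0\\.98 \\*")   # rho = 1 - 12/(8*63), starred
  expect_error(correlation_wide(correlation_matrix(d)), "single method")
})
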