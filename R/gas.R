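#' Convert cumulative gas pressure to gas volume
#'
#' ANKOM-style modules record cumulative head-space pressure (psi). The
#' amount of gas is obtained from the ideal gas law,
#' \eqn{n = P V_{head} / (R T)}, with the pressure in Pa
#' (1 psi = 6894.76 Pa), the head-space volume in m^3 and the incubation
#' temperature in K. By Avogadro's law one mole occupies 22,414 mL at
#' standard temperature and pressure, the default reporting basis;
#' `reference = "incubation"` instead reports the volume the gas would
#' occupy at the incubation temperature and 101,325 Pa.
#'
#' @param pressure Cumulative pressure(s), psi. Non-negative.
#' @param headspace Head-space volume in mL (default 106, the standard
#'   fermenter bottle).
#' @param temperature Incubation temperature in degrees Celsius
#'   (default 39).
#' @param reference `"STP"` (default) or `"incubation"`.
#' @return Gas volume(s) in mL; linear and homogeneous in `pressure` and
#'   `headspace`.
#' @examples
#' pressure_to_volume(1)           # ~6.31 mL per psi at 39 C, 106 mL headspace
#' @export
pressure_to_volume <- function(pressure, headspace = 106, temperature = 39,
                               reference = c("STP", "incubation")) {
  reference <- match.arg(reference)
  if (any(pressure < 0, na.rm = TRUE)) abort("Negative pressure rejected.")
  if (headspace <= 0) abort("`headspace` must be positive (mL).")
  if (temperature <= -273.15) abort("`temperature` below absolute zero.")
  t_k <- temperature + 273.15
  moles <- (pressure * 6894.76) * (headspace * 1e-6) / (8.314 * t_k)
  switch(reference,
    STP = moles * 22414,
    incubation = moles * 8.314 * t_k / 101325 * 1e6
  )
}

#' Blank-correct gas curves
#'
#' Subtracts the pointwise mean pressure of the blank fermenters (inoculum
#' without substrate) from each test curve, in the pressure domain, before
#' any volume conversion. Blank grids that do not align with a test grid
#' are linearly interpolated onto it. Corrected values may be negative and
#' are preserved as such.
#'
#' @param curves Tidy gas table: columns `fermenter`, `time_h`,
#'   `cum_pressure_psi` (plus any id columns, kept).
#' @param blanks Tidy gas table of blank fermenters, same columns.
#' @return `curves` with `cum_pressure_psi` replaced by the blank-corrected
#'   pressure.
#' @export
blank_correct <- function(curves, blanks) {
  curves <- as_tibble(curves)
  blanks <- as_tibble(blanks)
  if (nrow(blanks) == 0) abort("`blanks` is empty.")
  bl <- blanks %>%
    group_by(.data$time_h) %>%
    summarise(blank_psi = mean(.data$cum_pressure_psi), .groups = "drop") %>%
    arrange(.data$time_h)
  lo <- max(min(curves$time_h), min(bl$time_h))
  hi <- min(max(curves$time_h), max(bl$time_h))
  if (lo > hi) abort("Test and blank curves share no overlapping time range.")
  bfun <- stats::approxfun(bl$time_h, bl$blank_psi, rule = 2)
  curves %>%
    mutate(cum_pressure_psi = .data$cum_pressure_psi - bfun(.data$time_h))
}

#' Downsample a gas curve to a coarser resolution
#'
#' The native recording interval of the pressure modules is 5 min; for curve
#' fitting the series is thinned to a coarser grid (0.5 h in the analysis
#' workflow) by keeping, for each grid point, the last observation at or
#' before it. The `t = 0` observation is always preserved.
#'
#' @param curve Tidy gas table with `time_h` (strictly increasing within a
#'   fermenter) and any value columns.
#' @param resolution Target grid spacing in hours; must exceed the native
#'   interval of the data.
#' @return The thinned tibble, one row per grid point per fermenter.
#' @export
downsample_curve <- function(curve, resolution = 0.5) {
  curve <- as_tibble(curve)
  if (nrow(curve) == 0) abort("Empty gas curve.")
  if (resolution <= 0) abort("`resolution` must be positive.")
  groups <- intersect(c("run", "fermenter", "variant"), names(curve))
  pick <- function(d) {
    d <- d %>% arrange(.data$time_h)
    native <- min(diff(unique(d$time_h)))
    if (is.finite(native) && resolution <= native)
      abort("`resolution` must be coarser than the native interval.")
    grid <- seq(min(d$time_h), max(d$time_h), by = resolution)
    idx <- vapply(grid, function(g) max(which(d$time_h <= g + 1e-9)), integer(1))
    d[unique(idx), , drop = FALSE] %>% mutate(time_h = grid[!duplicated(idx)])
  }
  if (length(groups) == 0) return(pick(curve))
  curve %>%
    group_by(across(dplyr::all_of(groups))) %>%
    dplyr::group_modify(~ pick(.x)) %>%
    ungroup()
}

#' Interpretable Gompertz gas-production parameters
#'
#' Cumulative gas production is modelled with a Gompertz curve expressed in
#' three interpretable parameters: `a`, the asymptotic gas production
#' (mL per g substrate dry matter); `b`, the time (h) by which one third of
#' `a` has been produced; and `c`, the additional time (h) from `b` until
#' 70% of `a` has been produced. Internally the curve is the standard
#' two-parameter Gompertz \eqn{G(t) = a \exp(-\exp(-(t - m)/s))}; the pair
#' `(m, s)` is the unique solution of the two defining constraints
#' \eqn{G(b) = a/3} and \eqn{G(b+c) = 0.7a} (see [abc_to_shape()]).
#'
#' @param a Asymptotic gas production, mL/g DM, positive.
#' @param b Time (h) to one third of `a`, positive.
#' @param c Time (h) from `b` to 70% of `a`, positive.
#' @return An object of class `gompertz_params`.
#' @examples
#' g <- gompertz_params(a = 200, b = 18.6, c = 8.5)
#' gompertz_value(g, c(18.6, 27.1))  # a/3 and 0.7 a by construction
#' @export
gompertz_params <- function(a, b, c) {
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      abort(sprintf("`%s` must be a single positive number.", nm))
  }
  shape <- abc_to_shape(b, c)
  structure(list(a = a, b = b, c = c, m = shape[["m"]], s = shape[["s"]]),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf(
    "Gompertz gas kinetics: a = %g mL/g DM, b = %g h, c = %g h (m = %.4g, s = %.4g)\n",
    x$a, x$b, x$c, x$m, x$s))
  invisible(x)
}

#' Map the interpretable (b, c) pair to Gompertz shape parameters
#'
#' Solves the constraints \eqn{G(b) = a/3} and \eqn{G(b+c) = 0.7a} for the
#' location `m` and scale `s` of \eqn{G(t) = a\exp(-\exp(-(t-m)/s))}:
#' \deqn{s = \frac{c}{\ln(\ln 3 / \ln(10/7))}, \qquad m = b + s \ln \ln 3.}
#' The asymptote cancels, so the mapping depends on `b` and `c` only.
#'
#' @param b,c Positive times in hours (see [gompertz_params()]).
#' @return Named numeric vector `c(m = , s = )`.
#' @export
abc_to_shape <- function(b, c) {
  if (any(b <= 0) || any(c <= 0)) abort("`b` and `c` must be positive.")
  b <- unname(b)
  s <- unname(c) / log(log(3) / log(10 / 7))
  m <- b + s * log(log(3))
  base::c(m = m, s = s)  # `c` is shadowed by the argument here
}

#' @rdname gompertz_params
#' @param params A `gompertz_params` object.
#' @param t Times in hours, non-negative.
#' @return `gompertz_value()` returns the modelled cumulative gas volume
#'   (mL/g DM) at `t`; strictly increasing in `t` with limit `a`.
#' @export
gompertz_value <- function(params, t) {
  stopifnot(inherits(params, "gompertz_params"))
  t <- check_times(t)
  params$a * exp(-exp(-(t - params$m) / params$s))
}

#' Fit the Gompertz gas-production model
#'
#' Least-squares fit of the interpretable Gompertz curve (see
#' [gompertz_params()]) to blank-corrected, dry-matter-normalised gas
#' volumes. Starting values are read off the empirical curve (maximum for
#' `a`, interpolated crossing times for `b` and `c`); optional seeded
#' multistarts guard against local minima.
#'
#' @param data Tidy table with `time_h` and `vol_ml_per_g` columns.
#' @param n_starts Seeded multistart perturbations (default 5).
#' @param start_seed Seed for the perturbations.
#' @param start Optional named starting values `c(a=, b=, c=)` overriding
#'   the empirical rule.
#' @param weights `"none"` (ordinary least squares, default) or
#'   `"proportional"` (residuals scaled by the predicted value), the latter
#'   appropriate when measurement error is relative rather than additive —
#'   unweighted Wald intervals undercover the asymptote under
#'   proportional error. RMSE and R2 are always reported in raw volume
#'   units.
#' @return A [rumen_fit] with terms `a`, `b`, `c`, plus `$params` (a
#'   `gompertz_params`) when converged.
#' @export
fit_gompertz <- function(data, n_starts = 5, start_seed = 1L, start = NULL,
                         weights = c("none", "proportional")) {
  weights <- match.arg(weights)
  d <- as_tibble(data)
  terms <- c("a", "b", "c")
  if (!all(c("time_h", "vol_ml_per_g") %in% names(d)))
    return(failed_fit("gompertz", "needs `time_h` and `vol_ml_per_g` columns",
                      terms = terms))
  d <- d %>% filter(!is.na(.data$vol_ml_per_g))
  if (length(unique(d$time_h)) < 5L)
    return(failed_fit("gompertz", "needs >= 5 distinct time points",
                      n_obs = nrow(d), terms = terms))
  if (max(d$vol_ml_per_g) - min(d$vol_ml_per_g) <= 0 ||
      max(abs(d$vol_ml_per_g)) == 0)
    return(failed_fit("gompertz", "degenerate (flat) gas curve",
                      n_obs = nrow(d), terms = terms))

  if (is.null(start)) start <- gompertz_start(d)
  predict_at <- function(par) {
    sh <- abc_to_shape(max(par[2], 1e-8), max(par[3], 1e-8))
    par[1] * exp(-exp(-(d$time_h - sh[["m"]]) / sh[["s"]]))
  }
  resid_fn <- function(par) {
    pred <- predict_at(par)
    r <- d$vol_ml_per_g - pred
    if (weights == "proportional") r / pmax(pred, 1e-8) else r
  }
  fit <- multistart_lm(resid_fn, start,
                       lower = c(1e-8, 1e-8, 1e-8), upper = rep(Inf, 3),
                       n_starts = n_starts, start_seed = start_seed)
  if (is.null(fit))
    return(failed_fit("gompertz", "optimiser did not converge",
                      n_obs = nrow(d), terms = terms))
  est <- wald_estimates(fit, terms, nrow(d))
  gof <- fit_gof(d$vol_ml_per_g - predict_at(fit$par), d$vol_ml_per_g, 3L)
  params <- gompertz_params(fit$par[[1]], fit$par[[2]], fit$par[[3]])
  new_rumen_fit(
    "gompertz", est, gof$rmse, gof$r2, converged = TRUE, n_obs = nrow(d),
    data = d %>% select("time_h", value = "vol_ml_per_g"),
    predict_fn = function(tgrid)
      tibble(time_h = tgrid, series = "fit",
             value = gompertz_value(params, tgrid)),
    extra = list(params = params)
  )
}

# empirical starting values: asymptote just above the observed maximum,
# crossing times of a/3 and 0.7 a by linear interpolation
gompertz_start <- function(d) {
  d <- d %>% arrange(.data$time_h)
  a0 <- max(d$vol_ml_per_g) * 1.05
  cross <- function(level) {
    i <- which(d$vol_ml_per_g >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(max(d$time_h[1], 1e-3))
    t1 <- d$time_h[i - 1]; t2 <- d$time_h[i]
    v1 <- d$vol_ml_per_g[i - 1]; v2 <- d$vol_ml_per_g[i]
    if (v2 == v1) return(t2)
    t1 + (level - v1) / (v2 - v1) * (t2 - t1)
  }
  b0 <- cross(a0 / 3)
  t70 <- cross(0.7 * a0)
  if (!is.finite(b0) || b0 <= 0) b0 <- stats::median(d$time_h)
  c0 <- if (is.finite(t70) && t70 > b0) t70 - b0 else b0 / 2
  c(a = a0, b = b0, c = max(c0, 1e-3))
}
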