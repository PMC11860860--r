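#' Fit the HGB-to-HGA conversion-clearance model
#'
#' Estimates the four parameters (`hga0`, `hgb0`, `k`, `l`) of the
#' precursor-product model by nonlinear least squares on the pooled HGA and
#' HGB observations. Residuals of the two analytes are weighted equally in
#' raw concentration units, i.e. a single ordinary-least-squares objective
#' over the stacked series. With `mode = "means"` replicate fermenters are
#' first averaged per time point and the mean profiles are fitted instead
#' of the individual measurements.
#'
#' Starting values follow a deterministic rule — initial concentrations
#' from the `t = 0` observations, `k` from the endpoint log-slope of HGB,
#' `l` from the post-peak log-slope of HGA — and the optimiser is restarted
#' from `n_starts` seeded perturbations (uniform within +/-50%) of that
#' guess; the restart with the smallest residual sum of squares wins.
#' Censored (below measurement range) observations are dropped from the
#' objective by default, or replaced by half their reporting limit with
#' `censored = "half_limit"`.
#'
#' @param data A tidy concentration table with at least `time_h`, `analyte`
#'   (must contain `"HGA"` and `"HGB"` rows) and `value`; optional logical
#'   `censored` and character `unit` columns are honoured.
#' @param mode `"individual"` (all measurements, default) or `"means"`
#'   (per-time-point means).
#' @param censored How to treat below-range observations: `"drop"` (default)
#'   or `"half_limit"` (substitute limit/2; the `value` of a censored row
#'   must hold the reporting limit).
#' @param n_starts Number of seeded multistart perturbations (default 10).
#' @param start_seed Seed for the multistart perturbations; the global RNG
#'   state is left untouched.
#' @return A [rumen_fit] object with terms `hga0`, `hgb0`, `k`, `l`. The
#'   fitted parameters are also available as a [toxin_kinetic_params()]
#'   object in `$params` when the fit converged.
#' @examples
#' truth <- toxin_kinetic_params(1, 10, k = 0.2, l = 0.1)
#' grid <- c(0, 1, 2, 4, 8, 24, 48)
#' obs <- tibble::tibble(
#'   time_h = rep(grid, 2),
#'   analyte = rep(c("HGA", "HGB"), each = length(grid)),
#'   value = c(hga_at(truth, grid), hgb_at(truth, grid))
#' )
#' fit <- fit_conversion_model(obs)
#' tidy(fit)
#' @export
fit_conversion_model <- function(data, mode = c("individual", "means"),
                                 censored = c("drop", "half_limit"),
                                 n_starts = 10, start_seed = 1L) {
  mode <- match.arg(mode)
  censored <- match.arg(censored)
  terms <- c("hga0", "hgb0", "k", "l")
  d <- prepare_conc(data, c("HGA", "HGB"), censored)
  if (!is.null(d$error))
    return(failed_fit("conversion_clearance", d$error, terms = terms))
  d <- d$data

  n_times <- length(unique(d$time_h))
  if (n_times < 4L)
    return(failed_fit(
      "conversion_clearance",
      sprintf("needs >= 4 distinct usable time points, got %d", n_times),
      n_obs = nrow(d), terms = terms))
  if (!all(c("HGA", "HGB") %in% d$analyte))
    return(failed_fit("conversion_clearance",
                      "both HGA and HGB observations are required",
                      n_obs = nrow(d), terms = terms))
  if (all(d$value[d$analyte == "HGB"] == 0))
    return(failed_fit(
      "conversion_clearance",
      "HGB is identically zero: conversion rate k is not identifiable",
      n_obs = nrow(d), terms = terms))

  if (mode == "means") {
    d <- d %>%
      group_by(.data$time_h, .data$analyte) %>%
      summarise(value = mean(.data$value), .groups = "drop")
  }

  resid_fn <- function(par) {
    p <- list(hga0 = par[1], hgb0 = par[2], k = max(par[3], 1e-12),
              l = max(par[4], 0), unit = "ug/mL")
    class(p) <- "toxin_kinetic_params"
    pred <- ifelse(d$analyte == "HGA",
                   hga_at(p, d$time_h),
                   hgb_at(p, d$time_h))
    d$value - pred
  }

  start <- conversion_start(d)
  fit <- multistart_lm(resid_fn, start,
                       lower = c(0, 0, 1e-10, 0),
                       upper = rep(Inf, 4),
                       n_starts = n_starts, start_seed = start_seed)
  if (is.null(fit))
    return(failed_fit("conversion_clearance", "optimiser did not converge",
                      n_obs = nrow(d), terms = terms))

  est <- wald_estimates(fit, terms, nrow(d))
  gof <- fit_gof(fit$fvec, d$value, 4L)
  params <- toxin_kinetic_params(max(fit$par[1], 0), max(fit$par[2], 0),
                                 max(fit$par[3], 1e-12), max(fit$par[4], 0))
  predict_fn <- function(tgrid) {
    bind_rows(
      tibble(time_h = tgrid, series = "HGA", value = hga_at(params, tgrid)),
      tibble(time_h = tgrid, series = "HGB", value = hgb_at(params, tgrid))
    )
  }
  new_rumen_fit(
    "conversion_clearance", est, gof$rmse, gof$r2,
    converged = TRUE, n_obs = nrow(d), mode = mode,
    data = d %>% rename(series = "analyte"),
    predict_fn = predict_fn,
    extra = list(params = params)
  )
}

# shared validation: keep requested analytes, resolve censoring policy
prepare_conc <- function(data, analytes, censored_policy) {
  data <- as_tibble(data)
  need <- c("time_h", "analyte", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    return(list(error = paste("missing columns:", paste(miss, collapse = ", "))))
  d <- data %>% filter(.data$analyte %in% analytes)
  if (!"censored" %in% names(d)) d$censored <- FALSE
  d$censored[is.na(d$censored)] <- FALSE
  if (nrow(d) == 0) return(list(error = "no observations for requested analytes"))
  if ("unit" %in% names(d) && length(unique(d$unit)) > 1)
    return(list(error = "mixed concentration units; convert_units() first"))
  if (censored_policy == "drop") {
    d <- d %>% filter(!.data$censored)
  } else {
    d <- d %>% mutate(value = ifelse(.data$censored, .data$value / 2, .data$value))
  }
  if (nrow(d) == 0) return(list(error = "all observations are censored"))
  if (anyNA(d$value)) return(list(error = "NA concentrations present"))
  list(data = d %>% select("time_h", "analyte", "value"))
}

# deterministic initial-guess rule for the conversion model
conversion_start <- function(d) {
  means <- d %>%
    group_by(.data$time_h, .data$analyte) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  t0 <- min(means$time_h)
  at0 <- function(a) {
    v <- means$value[means$analyte == a & means$time_h == t0]
    if (length(v) == 0) 0 else v[1]
  }
  hga0 <- max(at0("HGA"), 1e-6)
  hgb0 <- max(at0("HGB"), 1e-6)

  hgb <- means %>% filter(.data$analyte == "HGB", .data$value > 0) %>%
    arrange(.data$time_h)
  k0 <- if (nrow(hgb) >= 2) {
    dt <- hgb$time_h[nrow(hgb)] - hgb$time_h[1]
    if (dt > 0) log(hgb$value[1] / hgb$value[nrow(hgb)]) / dt else NA_real_
  } else NA_real_
  if (!is.finite(k0) || k0 <= 0) k0 <- 0.1

  hga <- means %>% filter(.data$analyte == "HGA", .data$value > 0) %>%
    arrange(.data$time_h)
  l0 <- NA_real_
  if (nrow(hga) >= 2) {
    ipk <- which.max(hga$value)
    if (ipk < nrow(hga)) {
      dt <- hga$time_h[nrow(hga)] - hga$time_h[ipk]
      if (dt > 0)
        l0 <- log(hga$value[ipk] / hga$value[nrow(hga)]) / dt
    }
  }
  if (!is.finite(l0) || l0 <= 0) l0 <- 0.05
  c(hga0 = hga0, hgb0 = hgb0, k = k0, l = l0)
}

# Levenberg-Marquardt with seeded multistart; returns the converged nls.lm
# object with the lowest deviance, or NULL if nothing converged.
multistart_lm <- function(resid_fn, start, lower, upper,
                          n_starts = 10, start_seed = 1L) {
  starts <- list(start)
  if (n_starts > 0) {
    perturbed <- withr::with_seed(start_seed, {
      lapply(seq_len(n_starts), function(i) {
        s <- start * stats::runif(length(start), 0.5, 1.5)
        pmin(pmax(s, lower + 1e-12), ifelse(is.finite(upper), upper, s))
      })
    })
    starts <- c(starts, perturbed)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (!fit$info %in% 1:4) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

#' Fit a single-exponential decay and estimate the half-life
#'
#' Fits \eqn{C(t) = C_0 e^{-kt}} to one analyte's concentration series by
#' nonlinear least squares and reports the half-life \eqn{t_{1/2} =
#' \ln 2 / k}. Used for the clearance of pure hypoglycin A and MCPrG in
#' batch cultures, where no precursor feeds the pool. Censored observations
#' are excluded (a message notes how many), and non-positive values cannot
#' contribute to the log-scale starting value.
#'
#' @param data A tidy concentration table with `time_h` and `value` columns;
#'   if an `analyte` column is present it must identify a single analyte or
#'   `analyte` must be given.
#' @param analyte Optional analyte name to select from `data`.
#' @return A [rumen_fit] with terms `c0` and `k`, plus `$half_life` (hours).
#'   Non-decreasing data yield `k <= 0` and are flagged as a failed fit.
#' @examples
#' d <- tibble::tibble(time_h = c(0, 8), value = c(564, 25.3))
#' fit <- fit_exponential_decay(d)
#' fit$half_life
#' @export
fit_exponential_decay <- function(data, analyte = NULL) {
  data <- as_tibble(data)
  if (!is.null(analyte)) data <- data %>% filter(.data$analyte == !!analyte)
  if ("analyte" %in% names(data) && length(unique(data$analyte)) > 1)
    abort("`data` holds several analytes; pick one with `analyte`.")
  if (!"censored" %in% names(data)) data$censored <- FALSE
  n_cens <- sum(data$censored, na.rm = TRUE)
  if (n_cens > 0)
    message(sprintf("fit_exponential_decay: excluding %d censored observation(s)",
                    n_cens))
  d <- data %>% filter(!.data$censored, .data$value > 0)
  terms <- c("c0", "k")
  if (length(unique(d$time_h)) < 2L)
    return(failed_fit("exponential_decay",
                      "needs >= 2 distinct time points with positive values",
                      n_obs = nrow(d), terms = terms))

  # log-linear regression gives the starting values (and is exact for
  # noise-free data)
  lf <- lm(log(value) ~ time_h, data = d)
  start <- c(c0 = exp(coef(lf)[[1]]), k = -coef(lf)[[2]])
  resid_fn <- function(par) d$value - par[1] * exp(-par[2] * d$time_h)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4)
    return(failed_fit("exponential_decay", "optimiser did not converge",
                      n_obs = nrow(d), terms = terms))
  k <- fit$par[[2]]
  # k of zero within floating tolerance over the observed span means the
  # series is not decaying at all
  if (!is.finite(k) || k <= 0 ||
      k * diff(range(d$time_h)) < sqrt(.Machine$double.eps))
    return(failed_fit("exponential_decay",
                      "estimated rate k <= 0: data are not decaying",
                      n_obs = nrow(d), terms = terms))
  est <- wald_estimates(fit, terms, nrow(d))
  gof <- fit_gof(fit$fvec, d$value, 2L)
  c0 <- fit$par[[1]]
  new_rumen_fit(
    "exponential_decay", est, gof$rmse, gof$r2,
    converged = TRUE, n_obs = nrow(d),
    data = d %>% select("time_h", "value"),
    predict_fn = function(tgrid)
      tibble(time_h = tgrid, series = "fit", value = c0 * exp(-k * tgrid)),
    extra = list(half_life = log(2) / k, c0 = c0, k = k)
  )
}
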