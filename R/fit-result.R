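#' Nonlinear fit results
#'
#' All nonlinear fits in the package (conversion-clearance kinetics,
#' single-exponential decay, Gompertz gas production) return a `rumen_fit`
#' object: point estimates with Wald-type 95% confidence intervals derived
#' from the Jacobian at the optimum, the root mean square error
#' (residual-degree-of-freedom convention, `sqrt(SSR/(n - p))`), a
#' coefficient of determination `1 - SSR/SStot`, and a convergence flag.
#' Failed or degenerate fits are returned with `converged = FALSE` and an
#' explanatory `message` rather than raising an error, so pipelines over
#' many fermenters keep running.
#'
#' @param x,object A `rumen_fit` object.
#' @param ... Unused, for generic consistency.
#' @name rumen_fit
NULL

new_rumen_fit <- function(model, estimates, rmse, r2, converged, n_obs,
                          mode = NA_character_, message = NULL,
                          data = NULL, predict_fn = NULL, extra = list()) {
  structure(
    c(list(
      model = model, estimates = estimates, rmse = rmse, r2 = r2,
      converged = converged, n_obs = n_obs, mode = mode,
      message = message, data = data, predict_fn = predict_fn
    ), extra),
    class = "rumen_fit"
  )
}

failed_fit <- function(model, message, n_obs = 0L, terms = character()) {
  est <- tibble(
    term = terms, estimate = NA_real_, std.error = NA_real_,
    conf.low = NA_real_, conf.high = NA_real_
  )
  new_rumen_fit(model, est, rmse = NA_real_, r2 = NA_real_,
                converged = FALSE, n_obs = n_obs, message = message)
}

# Wald-type estimate table from an nls.lm fit.
# Falls back to NA std errors when the Jacobian is rank-deficient.
wald_estimates <- function(fit, terms, n_obs) {
  est <- fit$par
  p <- length(est)
  se <- rep(NA_real_, p)
  ssr <- fit$deviance
  dfres <- max(n_obs - p, 1L)
  hess <- fit$hessian
  cov_ok <- tryCatch({
    covm <- solve(hess) * ssr / dfres
    se <- sqrt(pmax(diag(covm), 0))
    TRUE
  }, error = function(e) FALSE)
  crit <- qt(0.975, dfres)
  tibble(
    term = terms,
    estimate = as.numeric(est),
    std.error = se,
    conf.low = as.numeric(est) - crit * se,
    conf.high = as.numeric(est) + crit * se
  )
}

fit_gof <- function(resid, obs, n_par) {
  n <- length(resid)
  ssr <- sum(resid^2)
  sstot <- sum((obs - mean(obs))^2)
  list(
    rmse = sqrt(ssr / max(n - n_par, 1L)),
    r2 = if (sstot > 0) 1 - ssr / sstot else NA_real_
  )
}

#' @rdname rumen_fit
#' @return `tidy()` returns a tibble with one row per model parameter:
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.rumen_fit <- function(x, ...) x$estimates

#' @rdname rumen_fit
#' @return `glance()` returns a one-row tibble with `model`, `rmse`, `r2`,
#'   `converged`, `n_obs` and `mode`.
#' @exportS3Method generics::glance
glance.rumen_fit <- function(x, ...) {
  tibble(model = x$model, rmse = x$rmse, r2 = x$r2,
         converged = x$converged, n_obs = x$n_obs, mode = x$mode)
}

#' @rdname rumen_fit
#' @export
print.rumen_fit <- function(x, ...) {
  cat(sprintf("<rumen_fit: %s>\n", x$model))
  if (!x$converged)
    cat("  NOT converged:", x$message %||% "unknown reason", "\n")
  print(as.data.frame(x$estimates), row.names = FALSE, digits = 4)
  cat(sprintf("  n = %d, RMSE = %s, R2 = %s\n", x$n_obs,
              format(x$rmse, digits = 4), format(x$r2, digits = 4)))
  invisible(x)
}

#' @rdname rumen_fit
#' @return `autoplot()` returns a ggplot of the observations overlaid with
#'   the fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.rumen_fit <- function(object, ...) {
  if (is.null(object$data) || is.null(object$predict_fn))
    abort("This fit carries no data to plot.")
  d <- object$data
  tgrid <- seq(min(d$time_h), max(d$time_h), length.out = 201)
  pred <- object$predict_fn(tgrid)   # tibble time_h, series, value
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line(data = pred, ggplot2::aes(colour = .data$series)) +
    ggplot2::labs(x = "Incubation time (h)", y = "Value",
                  colour = NULL, title = object$model) +
    ggplot2::theme_minimal()
  if ("series" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$series))
  } else {
    p + ggplot2::geom_point()
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
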