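#' Convert concentration units
#'
#' Rescales a tidy concentration table between ng/mL and ug/mL (factor of
#' exactly 10^3). Censored rows hold their reporting limit in `value`, so
#' limits are converted identically; the `censored` flag is untouched.
#' Converting a table already in the target unit is the identity.
#'
#' @param data Tidy concentration table with `value` and `unit` columns.
#' @param to Target unit, `"ng/mL"` or `"ug/mL"`.
#' @return The table with rescaled `value` and updated `unit`.
#' @examples
#' d <- tibble::tibble(value = 564, unit = "ng/mL", censored = FALSE)
#' convert_units(d, "ug/mL")$value  # 0.564
#' @export
convert_units <- function(data, to) {
  to <- check_conc_unit(to)
  data <- as_tibble(data)
  if (!all(c("value", "unit") %in% names(data)))
    abort("`data` needs `value` and `unit` columns.")
  from <- check_conc_unit(data$unit)
  factor <- dplyr::case_when(
    from == to ~ 1,
    from == "ng/mL" & to == "ug/mL" ~ 1e-3,
    from == "ug/mL" & to == "ng/mL" ~ 1e3
  )
  data %>% mutate(value = .data$value * factor, unit = to)
}

conc_cols <- c("run", "fermenter", "variant", "medium", "time_h",
               "analyte", "value", "unit", "censored")

#' Read and write tidy concentration tables
#'
#' The on-disk dialect is a plain UTF-8 CSV with "." as decimal separator
#' and the header `run,fermenter,variant,medium,time_h,analyte,value,unit,
#' censored`. Schema violations are reported with the offending columns.
#'
#' @param data Tidy concentration table.
#' @param path File path.
#' @return `read_concentration_csv()` returns the validated tibble;
#'   `write_concentration_csv()` returns `path` invisibly.
#' @export
write_concentration_csv <- function(data, path) {
  miss <- setdiff(conc_cols, names(data))
  if (length(miss) > 0)
    abort(paste("missing columns:", paste(miss, collapse = ", ")))
  readr::write_csv(data[conc_cols], path)
  invisible(path)
}

#' @rdname write_concentration_csv
#' @export
read_concentration_csv <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(conc_cols, hdr)
  if (length(miss) > 0)
    abort(paste("missing columns:", paste(miss, collapse = ", ")))
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         run = readr::col_integer(),
                         fermenter = readr::col_character(),
                         variant = readr::col_character(),
                         medium = readr::col_character(),
                         time_h = readr::col_double(),
                         analyte = readr::col_character(),
                         value = readr::col_double(),
                         unit = readr::col_character(),
                         censored = readr::col_logical()))
  probs <- readr::problems(d)
  if (nrow(probs) > 0)
    abort(sprintf("Malformed concentration CSV, first problem at row %d: %s",
                  probs$row[1], probs$expected[1]))
  miss <- setdiff(conc_cols, names(d))
  if (length(miss) > 0)
    abort(paste("missing columns:", paste(miss, collapse = ", ")))
  dup <- d %>% dplyr::count(.data$fermenter, .data$time_h, .data$analyte) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort("Duplicate (fermenter, time, analyte) records in CSV.")
  d
}

#' Read and write gas-curve tables
#'
#' Gas curves are stored as CSV with the columns `run,fermenter,variant,
#' time_h,cum_pressure_psi` preceded by `#`-prefixed metadata lines for the
#' head-space volume, incubation temperature and substrate dry matter.
#'
#' @param data Tidy gas table as produced by [generate_gas_curves()].
#' @param path File path.
#' @return `read_gas_csv()` returns the tibble with the metadata expanded
#'   back into columns.
#' @export
write_gas_csv <- function(data, path) {
  meta <- sprintf("# headspace_ml=%g\n# temp_c=%g\n# substrate_dm_g=%s\n",
                  data$headspace_ml[1], data$temp_c[1],
                  paste(unique(stats::na.omit(data$substrate_dm_g)),
                        collapse = ";"))
  body <- readr::format_csv(
    data[c("run", "fermenter", "variant", "time_h", "cum_pressure_psi",
           "substrate_dm_g")])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sub("\n$", "", meta), con)
  writeLines(sub("\n$", "", body), con)
  invisible(path)
}

#' @rdname write_gas_csv
#' @export
read_gas_csv <- function(path) {
  lines <- readr::read_lines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# *", key, "="), meta, value = TRUE)
    if (length(m) == 0) return(NA_real_)
    as.numeric(sub(paste0("^# *", key, "="), "", m[1]))
  }
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  d$headspace_ml <- get_meta("headspace_ml")
  d$temp_c <- get_meta("temp_c")
  as_tibble(d)
}

# serializable summary of a rumen_fit
fit_to_list <- function(fit) {
  est <- fit$estimates
  list(
    model = fit$model,
    parameters = as.list(setNames(est$estimate, est$term)),
    ci95 = setNames(lapply(seq_len(nrow(est)), function(i)
      c(est$conf.low[i], est$conf.high[i])), est$term),
    rmse = fit$rmse, r2 = fit$r2, converged = fit$converged,
    n_obs = fit$n_obs, mode = fit$mode, message = fit$message
  )
}

#' Write a fit report as JSON
#'
#' @param fit A [rumen_fit] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full batch-culture analysis pipeline
#'
#' Generates (or accepts) a synthetic experiment and pushes it through
#' every analysis stage: conversion-clearance kinetics for the seed
#' incubations (with the predicted HGA peak time), exponential decay and
#' half-lives for the pure-toxin incubations, blank-corrected and
#' downsampled Gompertz gas fits per variant, metabolite summaries (NH3 net
#' difference, per-fermenter C2:C3 ratio) and the correlation tables at the
#' configured time point. When `out_dir` is given, one JSON report per
#' stage plus a combined summary are written; re-running with the same
#' configuration and seed reproduces them byte-identically.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param out_dir Optional output directory for the JSON reports.
#' @param experiment Optional pre-generated [generate_experiment()] result;
#'   when supplied, no new data are generated.
#' @param fit_mode `"individual"` or `"means"`, passed to
#'   [fit_conversion_model()].
#' @param correlation_time Time point (h) for the correlation stage
#'   (default 24).
#' @param correlation_methods Correlation families to compute.
#' @return A list with elements `kinetics`, `gas`, `metabolites`,
#'   `correlations`, `summary` and `ok` (TRUE when every stage converged).
#' @export
run_pipeline <- function(config = experiment_config(), seed = config$seed,
                         out_dir = NULL, experiment = NULL,
                         fit_mode = c("individual", "means"),
                         correlation_time = 24,
                         correlation_methods = c("pearson", "spearman",
                                                 "kendall")) {
  fit_mode <- match.arg(fit_mode)
  if (is.null(experiment)) experiment <- generate_experiment(config, seed)
  stopifnot(inherits(experiment, "synthetic_experiment"))
  tox <- experiment$toxins
  gas <- experiment$gas
  met <- experiment$metabolites

  # --- toxin kinetics ------------------------------------------------
  kinetics <- list()
  if ("SMS" %in% config$variants) {
    sms <- tox %>% filter(.data$variant == "SMS", .data$medium == "vital")
    conv <- fit_conversion_model(sms, mode = fit_mode)
    peak <- if (conv$converged) hga_peak_time(conv$params) else NA_real_
    kinetics$sms_conversion <- c(fit_to_list(conv),
                                 list(hga_peak_time_h = peak))
  }
  if ("PCM" %in% config$variants) {
    pcm <- tox %>% filter(.data$variant == "PCM", .data$medium == "vital")
    for (a in c("HGA", "MCPrG")) {
      dec <- fit_exponential_decay(pcm, analyte = a)
      kinetics[[paste0("pcm_", tolower(a), "_decay")]] <-
        c(fit_to_list(dec), list(half_life_h = dec$half_life %||% NA_real_))
    }
  }

  # --- gas production ------------------------------------------------
  tests <- gas %>% filter(.data$variant != "BLANK")
  blanks <- gas %>% filter(.data$variant == "BLANK")
  corrected <- blank_correct(tests, blanks) %>% downsample_curve(0.5)
  volumes <- corrected %>%
    mutate(vol_ml_per_g = pressure_to_volume(
      pmax(.data$cum_pressure_psi, 0),
      headspace = .data$headspace_ml[1],
      temperature = .data$temp_c[1]) / .data$substrate_dm_g)
  gas_fits <- lapply(setNames(config$variants, config$variants), function(v)
    fit_gompertz(volumes %>% filter(.data$variant == v)))
  gas_report <- lapply(gas_fits, fit_to_list)

  # --- metabolites ----------------------------------------------------
  met_tests <- met %>% filter(.data$variant != "BLANK")
  met_blanks <- met %>% filter(.data$variant == "BLANK")
  adjusted <- nh3_difference(met_tests, met_blanks) %>% c2_c3_ratio()
  met_summary <- adjusted %>%
    filter(.data$time_h %in% range(config$grid)) %>%
    group_by(.data$variant, .data$time_h, .data$analyte) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE), .groups = "drop")

  # --- correlations ---------------------------------------------------
  with_key <- function(d) d %>%
    mutate(fermenter = sprintf("R%d_%s", .data$run,
                               sub("^.*(\\d+)$", "\\1", .data$fermenter)))
  correlations <- list()
  for (v in intersect(config$variants, c("PCM", "SMS"))) {
    tox_v <- tox %>%
      filter(.data$variant == v, .data$medium == "vital",
             !.data$censored) %>%
      select("run", "fermenter", "time_h", "analyte", "value") %>%
      with_key()
    met_v <- adjusted %>% filter(.data$variant == v) %>%
      select("run", "fermenter", "time_h", "analyte", "value") %>%
      with_key()
    combined <- bind_rows(tox_v, met_v)
    correlations[[v]] <- purrr::map_dfr(correlation_methods, function(m)
      correlation_matrix(combined, time_h = correlation_time, method = m))
  }

  ok <- all(vapply(kinetics, function(k) isTRUE(k$converged), logical(1)),
            vapply(gas_report, function(g) isTRUE(g$converged), logical(1)))
  summary <- list(
    seed = as.integer(seed), fit_mode = fit_mode,
    n_toxin_records = nrow(tox), n_gas_records = nrow(gas),
    n_metabolite_records = nrow(met),
    variants = config$variants, ok = ok
  )
  result <- list(kinetics = kinetics, gas = gas_report,
                 metabolites = met_summary, correlations = correlations,
                 gas_fits = gas_fits, summary = summary, ok = ok)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wj <- function(x, f) jsonlite::write_json(
      x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA,
      null = "null", pretty = TRUE)
    wj(kinetics, "kinetics.json")
    wj(gas_report, "gas.json")
    wj(met_summary, "metabolites.json")
    wj(lapply(correlations, identity), "correlations.json")
    wj(summary, "summary.json")
  }
  invisible(result)
}

#' Serialize and restore an experiment configuration
#'
#' The configuration is the truth record of a synthetic dataset; these
#' helpers round-trip it through JSON so generated data can be regenerated
#' bit-identically later.
#'
#' @param config An [experiment_config()].
#' @param path JSON file path.
#' @return `read_config_json()` returns the restored `experiment_config`.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- experiment_config(
    n_runs = raw$n_runs, n_dup = raw$n_dup, grid = raw$grid,
    variants = raw$variants, media = raw$media,
    censor_limit_ng = raw$censor_limit_ng,
    autoclave_attenuation = raw$autoclave_attenuation,
    run_cv_multiplier = raw$run_cv_multiplier,
    gas_noise_sd = raw$gas$noise_sd, blank_drift = raw$gas$blank_drift,
    metabolite_noise = raw$metabolites$noise, seed = raw$seed
  )
  # restore possibly customised truth and noise tables verbatim
  cfg$conversion_truth <- as_tibble(raw$conversion_truth)
  cfg$decay_truth <- as_tibble(raw$decay_truth)
  cfg$cv <- as_tibble(raw$cv)
  cfg$gas$truth <- as_tibble(raw$gas$truth)
  cfg$gas$dm_g <- unlist(raw$gas$dm_g)
  cfg$metabolites$anchors <- as_tibble(raw$metabolites$anchors)
  cfg
}
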