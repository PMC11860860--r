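#' Configuration of a synthetic batch-culture experiment
#'
#' Bundles every generating parameter of the synthetic experiment: the
#' study design (4 consecutive runs, duplicate fermenters per variant,
#' sampling at 0/1/2/4/8/24/48 h, variants CSM/PCM/SMS in vital medium plus
#' autoclaved controls sampled at 0 and 48 h), the kinetic truth per
#' variant and medium, the gas-production truth per variant, endpoint
#' anchors for the fermentation metabolites, and the noise and censoring
#' model. The default truth reproduces the reported study conditions:
#' initial toxin concentrations and their dispersions, pure-toxin
#' half-lives of 2.05 h (HGA) and 2.20 h (MCPrG), conversion-clearance
#' rates calibrated so that the seed incubations peak at 13.7 h and retain
#' 5.6 ug/mL HGA at 48 h, and the published Gompertz gas parameters.
#'
#' The configuration, together with a seed, fully determines the generated
#' dataset; each fermenter draws from its own deterministic substream, so
#' subsetting runs or variants does not shift the draws of the others.
#'
#' @param n_runs Number of consecutive runs (default 4).
#' @param n_dup Duplicate fermenters per variant and run (default 2).
#' @param grid Sampling grid in hours, starting at 0
#'   (default `c(0, 1, 2, 4, 8, 24, 48)`).
#' @param variants Substrate variants (default CSM, PCM, SMS).
#' @param media Media to generate (default vital plus autoclaved controls).
#' @param toxin_cv `NULL` to use the per-analyte coefficients of variation
#'   implied by the reported 0 h means and SDs, or a single number applied
#'   to every toxin observation (0 disables noise).
#' @param censor_limit_ng Lower limit of quantification in ng/mL
#'   (default 0.5, the lowest matrix-matched calibration level); converted
#'   to each series' working unit.
#' @param autoclave_attenuation Multiplier on all rate constants in
#'   autoclaved medium (default 0.25), expressing that transformation still
#'   occurs abiotically but more slowly.
#' @param run_cv_multiplier Optional extra lognormal CV applied once per
#'   run and analyte (default 0: single pooled CV).
#' @param sms_k,sms_l Conversion and clearance rate constants (1/h) of the
#'   seed-incubation conversion-clearance truth.
#' @param gas_noise_sd Additive pressure noise SD in psi (default 0.05).
#' @param blank_drift Blank background pressure drift, psi/h (default 0.02).
#' @param metabolite_noise Multiplier on the anchor standard errors used as
#'   Gaussian noise SDs for pH/redox/SCFA/NH3 (default 1; 0 disables noise).
#' @param seed Default integer seed.
#' @return An `experiment_config` object (a validated named list).
#' @export
experiment_config <- function(n_runs = 4, n_dup = 2,
                              grid = c(0, 1, 2, 4, 8, 24, 48),
                              variants = c("CSM", "PCM", "SMS"),
                              media = c("vital", "autoclaved"),
                              toxin_cv = NULL,
                              censor_limit_ng = 0.5,
                              autoclave_attenuation = 0.25,
                              run_cv_multiplier = 0,
                              sms_k = 0.093, sms_l = 0.039,
                              gas_noise_sd = 0.05,
                              blank_drift = 0.02,
                              metabolite_noise = 1,
                              seed = 1L) {
  if (length(grid) < 1 || grid[1] != 0 || is.unsorted(grid, strictly = TRUE))
    abort("`grid` must be strictly increasing and start at 0.")
  if (!is.null(toxin_cv) && (length(toxin_cv) != 1 || toxin_cv < 0))
    abort("`toxin_cv` must be NULL or a single non-negative number.")
  if (run_cv_multiplier < 0) abort("`run_cv_multiplier` must be >= 0.")
  variants <- match.arg(variants, c("CSM", "PCM", "SMS"), several.ok = TRUE)
  media <- match.arg(media, c("vital", "autoclaved"), several.ok = TRUE)

  init <- reference_toxin_initials()
  att <- autoclave_attenuation

  # conversion-clearance truth (seed incubations, HGA/HGB)
  sms0 <- function(med, a) init$c0[init$variant == "SMS" &
                                     init$medium == med & init$analyte == a]
  conversion_truth <- tibble(
    variant = "SMS",
    medium = c("vital", "autoclaved"),
    hga0 = c(sms0("vital", "HGA"), sms0("autoclaved", "HGA")),
    hgb0 = c(sms0("vital", "HGB"), sms0("autoclaved", "HGB")),
    k = c(sms_k, sms_k * att),
    l = c(sms_l, sms_l * att),
    unit = "ug/mL"
  )

  # single-exponential truth (pure-toxin incubations and MCPrG everywhere)
  k_hga <- log(2) / 2.05     # reported half-life of pure HGA
  k_mcprg <- log(2) / 2.20   # reported half-life of pure MCPrG
  # seed-borne MCPrG declines from 1.2 to 0.32 ug/mL over 48 h
  k_mcprg_sms <- log(1.2 / 0.32) / 48
  pcm0 <- function(med, a) init$c0[init$variant == "PCM" &
                                     init$medium == med & init$analyte == a]
  decay_truth <- tibble(
    variant = c("PCM", "PCM", "PCM", "PCM", "SMS", "SMS"),
    medium = c("vital", "vital", "autoclaved", "autoclaved",
               "vital", "autoclaved"),
    analyte = c("HGA", "MCPrG", "HGA", "MCPrG", "MCPrG", "MCPrG"),
    c0 = c(pcm0("vital", "HGA"), pcm0("vital", "MCPrG"),
           pcm0("autoclaved", "HGA"), pcm0("autoclaved", "MCPrG"),
           sms0("vital", "MCPrG"), sms0("autoclaved", "MCPrG")),
    k = c(k_hga, k_mcprg, k_hga * att, k_mcprg * att,
          k_mcprg_sms, k_mcprg_sms * att),
    unit = c("ng/mL", "ng/mL", "ng/mL", "ng/mL", "ug/mL", "ug/mL")
  )

  cv_table <- init %>%
    mutate(cv = .data$c0_sd / .data$c0) %>%
    select("variant", "medium", "analyte", "cv")
  if (!is.null(toxin_cv)) cv_table$cv <- toxin_cv

  gas <- list(
    truth = reference_gas_kinetics(),
    headspace_ml = 106, temp_c = 39,
    dm_g = c(CSM = 0.2, PCM = 0.2, SMS = 0.3),
    native_interval_h = 1 / 12, duration_h = 48,
    noise_sd = gas_noise_sd, blank_drift = blank_drift, n_blanks = 4
  )

  metabolites <- list(
    anchors = reference_metabolite_anchors(),
    noise = metabolite_noise,
    blank_nh3 = c(v0 = 11, v48 = 18),  # background NH3 of the inoculum
    ph_range = c(6, 8)
  )

  structure(list(
    n_runs = as.integer(n_runs), n_dup = as.integer(n_dup), grid = grid,
    variants = variants, media = media,
    conversion_truth = conversion_truth, decay_truth = decay_truth,
    cv = cv_table, censor_limit_ng = censor_limit_ng,
    autoclave_attenuation = att, run_cv_multiplier = run_cv_multiplier,
    gas = gas, metabolites = metabolites, seed = as.integer(seed)
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic batch-culture experiment: %d runs x %d duplicates, %d time points\n",
    x$n_runs, x$n_dup, length(x$grid)))
  cat("  variants:", paste(x$variants, collapse = ", "),
      "| media:", paste(x$media, collapse = ", "), "\n")
  invisible(x)
}

# deterministic per-unit substream seed, independent of generation order
stream_seed <- function(seed, key) {
  mult <- c(100003, 10007, 101, 13)
  as.integer((abs(seed) + sum(key * mult[seq_along(key)])) %% 2147483647)
}

# mean-one multiplicative lognormal noise at a given CV
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

variant_index <- function(v) match(v, c("CSM", "PCM", "SMS", "BLANK"))
medium_index <- function(m) match(m, c("vital", "autoclaved"))

#' Generate toxin concentration series
#'
#' Draws the full toxin dataset of the synthetic experiment: seed
#' incubations (SMS) follow the conversion-clearance model for HGA/HGB and
#' a slow single-exponential for MCPrG; pure-toxin incubations (PCM) follow
#' single-exponential decay of HGA and MCPrG; autoclaved controls use
#' attenuated rate constants and are sampled only at the first and last
#' grid point. Observation noise is multiplicative lognormal with unit mean
#' at the configured CV, and values below the limit of quantification are
#' returned at the limit with `censored = TRUE`.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Tidy tibble `(run, fermenter, variant, medium, time_h, analyte,
#'   value, unit, censored)`.
#' @export
generate_toxin_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- config$grid
  grid_auto <- range(grid)
  analytes <- c("HGA", "HGB", "MCPrG")
  out <- list()
  for (run in seq_len(config$n_runs)) {
    # optional between-run variance component: one lognormal factor per
    # run and analyte, from a run-level stream
    run_fac <- setNames(rep(1, 3), analytes)
    if (config$run_cv_multiplier > 0) {
      run_fac <- withr::with_seed(
        stream_seed(seed, c(run, 9, 9, 0)),
        setNames(lognormal_factor(3, config$run_cv_multiplier), analytes))
    }
    for (v in intersect(config$variants, c("PCM", "SMS"))) {
      for (med in config$media) {
        tgrid <- if (med == "vital") grid else grid_auto
        for (dup in seq_len(config$n_dup)) {
          key <- c(run, variant_index(v), medium_index(med), dup)
          sseed <- stream_seed(seed, key)
          ferm <- sprintf("R%d_%s_%s_F%d", run, v, substr(med, 1, 3), dup)
          out[[length(out) + 1L]] <- withr::with_seed(
            sseed,
            draw_fermenter_toxins(config, run, ferm, v, med, tgrid, run_fac))
        }
      }
    }
  }
  bind_rows(out)
}

draw_fermenter_toxins <- function(config, run, ferm, variant, medium, tgrid,
                                  run_fac = c(HGA = 1, HGB = 1, MCPrG = 1)) {
  rows <- list()
  conv <- config$conversion_truth %>%
    filter(.data$variant == !!variant, .data$medium == !!medium)
  if (nrow(conv) == 1) {
    p <- toxin_kinetic_params(conv$hga0, conv$hgb0, conv$k, conv$l, conv$unit)
    rows[[1]] <- tibble(analyte = "HGA", time_h = tgrid,
                        mean = hga_at(p, tgrid), unit = conv$unit)
    rows[[2]] <- tibble(analyte = "HGB", time_h = tgrid,
                        mean = hgb_at(p, tgrid), unit = conv$unit)
  }
  dec <- config$decay_truth %>%
    filter(.data$variant == !!variant, .data$medium == !!medium)
  for (i in seq_len(nrow(dec))) {
    rows[[length(rows) + 1L]] <- tibble(
      analyte = dec$analyte[i], time_h = tgrid,
      mean = dec$c0[i] * exp(-dec$k[i] * tgrid), unit = dec$unit[i])
  }
  d <- bind_rows(rows)
  if (nrow(d) == 0) return(tibble())
  cvs <- config$cv %>%
    filter(.data$variant == !!variant, .data$medium == !!medium) %>%
    select("analyte", "cv")
  d <- d %>% left_join(cvs, by = "analyte") %>%
    mutate(cv = ifelse(is.na(.data$cv), 0, .data$cv))
  sdlog <- sqrt(log(1 + d$cv^2))
  d$value <- d$mean * unname(run_fac[d$analyte]) *
    rlnorm(nrow(d), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  limit <- ifelse(d$unit == "ng/mL", config$censor_limit_ng,
                  config$censor_limit_ng / 1000)
  d %>%
    mutate(
      censored = .data$value < limit,
      value = ifelse(.data$censored, limit, .data$value),
      run = run, fermenter = ferm, variant = variant, medium = medium
    ) %>%
    select("run", "fermenter", "variant", "medium", "time_h",
           "analyte", "value", "unit", "censored")
}

#' Generate cumulative gas-pressure curves
#'
#' Produces 5-min-interval cumulative pressure recordings for every vital
#' fermenter (autoclaved controls produce no appreciable gas and are
#' omitted) plus the per-run blank fermenters. The substrate signal is the
#' variant's Gompertz truth scaled by the substrate dry matter and
#' converted from volume to pressure by inverting the ideal-gas relation at
#' the configured head space and temperature; blanks contribute a slow
#' background drift. Additive Gaussian measurement noise is applied and the
#' recording is kept cumulative (non-negative, non-decreasing), as the
#' pressure modules report it.
#'
#' @inheritParams generate_toxin_experiment
#' @return Tidy tibble `(run, fermenter, variant, time_h, cum_pressure_psi,
#'   headspace_ml, temp_c, substrate_dm_g)`; blanks have
#'   `variant = "BLANK"` and `substrate_dm_g = NA`.
#' @export
generate_gas_curves <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  g <- config$gas
  tgrid <- seq(0, g$duration_h, by = g$native_interval_h)
  per_psi <- pressure_to_volume(1, g$headspace_ml, g$temp_c)
  out <- list()
  for (run in seq_len(config$n_runs)) {
    for (v in config$variants) {
      row <- g$truth %>% filter(.data$variant == v)
      gp <- gompertz_params(row$a, row$b, row$c)
      signal <- gompertz_value(gp, tgrid) * g$dm_g[[v]] / per_psi
      for (dup in seq_len(config$n_dup)) {
        key <- c(run, variant_index(v), 3, dup)
        psi <- withr::with_seed(stream_seed(seed, key), {
          raw <- signal + g$blank_drift * tgrid +
            rnorm(length(tgrid), 0, g$noise_sd)
          cummax(pmax(raw, 0))
        })
        out[[length(out) + 1L]] <- tibble(
          run = run, fermenter = sprintf("R%d_%s_G%d", run, v, dup),
          variant = v, time_h = tgrid, cum_pressure_psi = psi,
          headspace_ml = g$headspace_ml, temp_c = g$temp_c,
          substrate_dm_g = g$dm_g[[v]])
      }
    }
    for (bl in seq_len(g$n_blanks)) {
      key <- c(run, variant_index("BLANK"), 3, bl)
      psi <- withr::with_seed(stream_seed(seed, key), {
        raw <- g$blank_drift * tgrid + rnorm(length(tgrid), 0, g$noise_sd)
        cummax(pmax(raw, 0))
      })
      out[[length(out) + 1L]] <- tibble(
        run = run, fermenter = sprintf("R%d_BLANK_G%d", run, bl),
        variant = "BLANK", time_h = tgrid, cum_pressure_psi = psi,
        headspace_ml = g$headspace_ml, temp_c = g$temp_c,
        substrate_dm_g = NA_real_)
    }
  }
  bind_rows(out)
}

#' Generate fermentation-metabolite profiles
#'
#' Each pH/redox/SCFA trajectory interpolates its variant's 0 h and 48 h
#' anchors along the variant's normalised Gompertz shape (fermentation
#' products accumulate as fermentation gas does), with Gaussian noise at
#' the anchor standard errors. NH3 is generated for blanks (background
#' trajectory of the inoculum) and for test fermenters such that the
#' test-minus-mean-blank difference follows the anchored net trajectory.
#' pH is clamped to the 6.0--8.0 range attainable in buffered batch
#' cultures.
#'
#' @inheritParams generate_toxin_experiment
#' @return Tidy tibble `(run, fermenter, variant, time_h, analyte, value)`;
#'   blank fermenters carry `variant = "BLANK"` and only NH3.
#' @export
generate_metabolite_profiles <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  m <- config$metabolites
  grid <- config$grid
  shapes <- lapply(setNames(config$variants, config$variants), function(v) {
    row <- config$gas$truth %>% filter(.data$variant == v)
    gp <- gompertz_params(row$a, row$b, row$c)
    gv <- gompertz_value(gp, grid)
    (gv - gv[1]) / (gv[length(grid)] - gv[1])
  })
  blank_traj <- m$blank_nh3[["v0"]] +
    (m$blank_nh3[["v48"]] - m$blank_nh3[["v0"]]) * shapes[["CSM"]]

  out <- list()
  for (run in seq_len(config$n_runs)) {
    for (v in config$variants) {
      anch <- m$anchors %>% filter(.data$variant == v)
      for (dup in seq_len(config$n_dup)) {
        key <- c(run, variant_index(v), 4, dup)
        vals <- withr::with_seed(stream_seed(seed, key), {
          purrr::pmap_dfr(anch, function(variant, analyte, v0, v48, se) {
            traj <- v0 + (v48 - v0) * shapes[[v]]
            if (analyte == "NH3") traj <- traj + blank_traj
            obs <- traj + rnorm(length(grid), 0, se * m$noise)
            if (analyte == "pH")
              obs <- pmin(pmax(obs, m$ph_range[1]), m$ph_range[2])
            tibble(time_h = grid, analyte = analyte, value = obs)
          })
        })
        out[[length(out) + 1L]] <- vals %>%
          mutate(run = run,
                 fermenter = sprintf("R%d_%s_M%d", run, v, dup),
                 variant = v) %>%
          select("run", "fermenter", "variant", "time_h", "analyte", "value")
      }
    }
    for (bl in seq_len(config$gas$n_blanks)) {
      key <- c(run, variant_index("BLANK"), 4, bl)
      obs <- withr::with_seed(stream_seed(seed, key),
        blank_traj + rnorm(length(grid), 0, 0.41 * m$noise))
      out[[length(out) + 1L]] <- tibble(
        run = run, fermenter = sprintf("R%d_BLANK_M%d", run, bl),
        variant = "BLANK", time_h = grid, analyte = "NH3", value = obs)
    }
  }
  bind_rows(out)
}

#' Generate a complete synthetic experiment
#'
#' Runs all three generators under one seed and returns the dataset
#' together with its truth record (the configuration itself, which holds
#' every generating parameter).
#'
#' @inheritParams generate_toxin_experiment
#' @return A `synthetic_experiment` list: `$toxins`, `$gas`, `$metabolites`,
#'   `$config`, `$seed`.
#' @export
generate_experiment <- function(config = experiment_config(),
                                seed = config$seed) {
  structure(list(
    toxins = generate_toxin_experiment(config, seed),
    gas = generate_gas_curves(config, seed),
    metabolites = generate_metabolite_profiles(config, seed),
    config = config, seed = as.integer(seed)
  ), class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic batch-culture experiment (seed", x$seed, ")\n")
  cat(sprintf("  toxins: %d records, gas: %d, metabolites: %d\n",
              nrow(x$toxins), nrow(x$gas), nrow(x$metabolites)))
  invisible(x)
}
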