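#' Seeded parameter-recovery study for the conversion-clearance fit
#'
#' Repeatedly simulates the seed-incubation design (4 runs x 2 duplicate
#' fermenters, sampling at 0/1/2/4/8/24/48 h by default) at a given
#' observation CV, refits the conversion-clearance model to each replicate
#' dataset, and reports how often the generating `k` and `l` fall inside the
#' reported Wald 95% intervals. This is the package's calibration check
#' that the asymptotic intervals are trustworthy under the study's noise
#' level.
#'
#' @param n_reps Number of simulated experiments (default 200).
#' @param cv Observation coefficient of variation (default 0.10).
#' @param config Experiment configuration; defaults to the seed-incubation
#'   (SMS, vital medium) design at the given `cv`.
#' @param seed Base seed; repetition `i` uses `seed + i`.
#' @param mode Fit mode passed to [fit_conversion_model()].
#' @return A list: `$results`, one row per repetition and parameter with
#'   the estimate, interval and a `covered` flag; `$coverage`, the per-
#'   parameter coverage proportions; `$truth`, the generating parameters.
#' @export
recovery_study <- function(n_reps = 200, cv = 0.10,
                           config = experiment_config(variants = "SMS",
                                                      media = "vital",
                                                      toxin_cv = cv),
                           seed = 1L, mode = "individual") {
  truth <- config$conversion_truth %>% filter(.data$medium == "vital")
  truth_vec <- c(hga0 = truth$hga0, hgb0 = truth$hgb0,
                 k = truth$k, l = truth$l)
  results <- purrr::map_dfr(seq_len(n_reps), function(i) {
    d <- generate_toxin_experiment(config, seed = seed + i) %>%
      filter(.data$variant == "SMS", .data$medium == "vital")
    fit <- fit_conversion_model(d, mode = mode)
    tidy(fit) %>%
      mutate(rep = i, converged = fit$converged,
             truth = truth_vec[.data$term],
             covered = .data$conf.low <= .data$truth &
               .data$truth <= .data$conf.high)
  })
  coverage <- results %>%
    filter(.data$converged) %>%
    group_by(.data$term) %>%
    summarise(coverage = mean(.data$covered), n = n(), .groups = "drop")
  list(results = results, coverage = coverage, truth = truth_vec)
}
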