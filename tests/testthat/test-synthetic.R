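small_config <- function(...) {
  experiment_config(n_runs = 2, ...)
}

test_that("the same configuration and seed regenerate identical datasets", {
  cfg <- small_config()
  a <- generate_experiment(cfg, seed = 3)
  b <- generate_experiment(cfg, seed = 3)
  expect_identical(a$toxins, b$toxins)
  expect_identical(a$gas, b$gas)
  expect_identical(a$metabolites, b$metabolites)
  c <- generate_toxin_experiment(cfg, seed = 4)
  expect_false(identical(a$toxins, c))
})

test_that("fermenter substreams are independent of the run subset", {
  full <- generate_toxin_experiment(experiment_config(n_runs = 4), seed = 5)
  one <- generate_toxin_experiment(experiment_config(n_runs = 1), seed = 5)
  expect_identical(one, dplyr::filter(full, run == 1))
})

test_that("zero CV yields the model values exactly", {
  cfg <- small_config(toxin_cv = 0)
  tox <- generate_toxin_experiment(cfg, seed = 1)
  truth <- cfg$conversion_truth[cfg$conversion_truth$medium == "vital", ]
  p <- toxin_kinetic_params(truth$hga0, truth$hgb0, truth$k, truth$l)
  sms_all <- dplyr::filter(tox, variant == "SMS", medium == "vital",
                           analyte == "HGA", run == 1)
  sms <- dplyr::filter(sms_all, fermenter == sms_all$fermenter[1])
  expect_equal(sms$value, hga_at(p, sms$time_h), tolerance = 1e-12)

  dec <- cfg$decay_truth
  k_hga <- dec$k[dec$variant == "PCM" & dec$medium == "vital" &
                   dec$analyte == "HGA"]
  pcm_all <- dplyr::filter(tox, variant == "PCM", medium == "vital",
                           analyte == "HGA", run == 1, !censored)
  pcm <- dplyr::filter(pcm_all, fermenter == pcm_all$fermenter[1])
  expect_equal(pcm$value, 564 * exp(-k_hga * pcm$time_h), tolerance = 1e-12)
})

test_that("values below the quantification limit are censored at the limit", {
  cfg <- small_config(toxin_cv = 0)
  tox <- generate_toxin_experiment(cfg, seed = 1)
  pcm48 <- dplyr::filter(tox, variant == "PCM", medium == "vital",
                         analyte == "HGA", time_h == 48)
  # 564 ng/mL decayed over 48 h at t1/2 2.05 h is far below 0.5 ng/mL
  expect_true(all(pcm48$censored))
  expect_true(all(pcm48$value == 0.5))
  sms <- dplyr::filter(tox, variant == "SMS", medium == "vital")
  expect_false(any(sms$censored))   # ug/mL scale stays quantifiable
})

test_that("autoclaved controls use attenuated rates on the 0/48 h grid", {
  cfg <- small_config(toxin_cv = 0)
  tox <- generate_toxin_experiment(cfg, seed = 1)
  auto <- dplyr::filter(tox, medium == "autoclaved")
  expect_setequal(unique(auto$time_h), c(0, 48))
  # attenuated decay leaves measurable residues at 48 h
  pcm_auto <- dplyr::filter(auto, variant == "PCM", analyte == "HGA",
                            time_h == 48)
  dec <- cfg$decay_truth
  k_auto <- dec$k[dec$variant == "PCM" & dec$medium == "autoclaved" &
                    dec$analyte == "HGA"]
  expect_equal(k_auto, log(2) / 2.05 * 0.25, tolerance = 1e-12)
  expect_equal(pcm_auto$value[1], 587 * exp(-k_auto * 48), tolerance = 1e-12)
})

test_that("generated decay means match the closed-form expectation", {
  # many fermenters at default CV: the 8 h mean approaches C0 * 2^(-8/t_half)
  cfg <- experiment_config(n_runs = 250, variants = "PCM", media = "vital")
  tox <- generate_toxin_experiment(cfg, seed = 21)
  at8 <- dplyr::filter(tox, analyte == "HGA", time_h == 8)
  dec <- cfg$decay_truth
  k <- dec$k[dec$analyte == "HGA" & dec$medium == "vital"]
  expected <- 564 * exp(-k * 8)
  se <- sd(at8$value) / sqrt(nrow(at8))
  expect_equal(nrow(at8), 500)
  expect_lt(abs(mean(at8$value) - expected), 3 * se)
})

test_that("noise-free gas curves refit to the generating truth end to end", {
  cfg <- experiment_config(n_runs = 1, gas_noise_sd = 0)
  gas <- generate_gas_curves(cfg, seed = 1)
  tests <- dplyr::filter(gas, variant != "BLANK")
  blanks <- dplyr::filter(gas, variant == "BLANK")
  vols <- blank_correct(tests, blanks) |>
    downsample_curve(0.5) |>
    dplyr::mutate(vol_ml_per_g = pressure_to_volume(
      pmax(cum_pressure_psi, 0), headspace = 106, temperature = 39) /
        substrate_dm_g)
  truth <- reference_gas_kinetics()
  for (v in c("CSM", "PCM", "SMS")) {
    fit <- fit_gompertz(dplyr::filter(vols, variant == v))
    expect_true(fit$converged)
    row <- truth[truth$variant == v, ]
    expect_equal(est_of(fit, "a"), row$a, tolerance = 1e-3)
    expect_equal(est_of(fit, "b"), row$b, tolerance = 1e-3)
    expect_equal(est_of(fit, "c"), row$c, tolerance = 1e-3)
  }
})

test_that("blank gas curves are background only and scale with the asymptote", {
  cfg <- experiment_config(n_runs = 1, gas_noise_sd = 0, blank_drift = 0)
  gas <- generate_gas_curves(cfg, seed = 1)
  blanks <- dplyr::filter(gas, variant == "BLANK")
  expect_true(all(blanks$cum_pressure_psi == 0))

  # with zero background, blank correction is the identity
  tests <- dplyr::filter(gas, variant == "CSM")
  corr <- blank_correct(tests, blanks)
  expect_equal(corr$cum_pressure_psi, tests$cum_pressure_psi)

  # doubling the configured asymptote doubles the signal
  cfg2 <- cfg
  cfg2$gas$truth$a <- cfg$gas$truth$a * 2
  gas2 <- generate_gas_curves(cfg2, seed = 1)
  t2 <- dplyr::filter(gas2, variant == "CSM")
  expect_equal(t2$cum_pressure_psi, 2 * tests$cum_pressure_psi,
               tolerance = 1e-9)
})

test_that("metabolite anchors are honoured exactly without noise", {
  cfg <- small_config(metabolite_noise = 0)
  met <- generate_metabolite_profiles(cfg, seed = 1)
  tests <- dplyr::filter(met, variant != "BLANK")
  blanks <- dplyr::filter(met, variant == "BLANK")
  adj <- nh3_difference(tests, blanks)
  anchors <- reference_metabolite_anchors()
  ends <- adj |>
    dplyr::filter(time_h %in% c(0, 48)) |>
    dplyr::group_by(variant, analyte, time_h) |>
    dplyr::summarise(value = mean(value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = time_h, values_from = value)
  joined <- dplyr::inner_join(ends, anchors, by = c("variant", "analyte"))
  expect_equal(nrow(joined), nrow(anchors))
  expect_equal(joined$`0`, joined$v0, tolerance = 1e-9)
  expect_equal(joined$`48`, joined$v48, tolerance = 1e-9)
})

test_that("pH stays within the buffered batch-culture range under noise", {
  met <- generate_metabolite_profiles(experiment_config(), seed = 2)
  ph <- dplyr::filter(met, analyte == "pH")
  expect_true(all(ph$value >= 6 & ph$value <= 8))
})

test_that("initial toxin draws reproduce the configured means and SDs", {
  cfg <- experiment_config(n_runs = 250, variants = "SMS", media = "vital")
  tox <- generate_toxin_experiment(cfg, seed = 17)
  at0 <- dplyr::filter(tox, time_h == 0)
  targets <- list(HGA = c(4.7, 1.4), HGB = c(19.9, 5.41), MCPrG = c(1.2, 0.33))
  for (a in names(targets)) {
    v <- at0$value[at0$analyte == a]
    n <- length(v)
    expect_equal(n, 500)
    se_mean <- targets[[a]][2] / sqrt(n)
    expect_lt(abs(mean(v) - targets[[a]][1]), 3 * se_mean)
    # SE of the SD from the exact lognormal kurtosis at the configured CV
    se_sd <- lognormal_sd_se(targets[[a]][1], targets[[a]][2], n)
    expect_lt(abs(sd(v) - targets[[a]][2]), 3 * se_sd)
  }
})

test_that("configuration validation rejects malformed designs", {
  expect_error(experiment_config(grid = c(1, 2)), "start at 0")
  expect_error(experiment_config(toxin_cv = -1), "non-negative")
  expect_error(experiment_config(variants = "XXX"), "arg")
  expect_error(experiment_config(run_cv_multiplier = -0.1), ">= 0")
})

test_that("the run-level variance multiplier adds between-run spread", {
  cfg0 <- experiment_config(n_runs = 4, variants = "SMS", media = "vital",
                            toxin_cv = 0)
  cfg1 <- experiment_config(n_runs = 4, variants = "SMS", media = "vital",
                            toxin_cv = 0, run_cv_multiplier = 0.3)
  t0 <- generate_toxin_experiment(cfg0, seed = 2)
  t1 <- generate_toxin_experiment(cfg1, seed = 2)
  spread0 <- sd(t0$value[t0$analyte == "HGB" & t0$time_h == 0])
  spread1 <- sd(t1$value[t1$analyte == "HGB" & t1$time_h == 0])
  expect_equal(spread0, 0)
  expect_gt(spread1, 0)
})
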