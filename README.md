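# rumentox

Kinetic analysis of sycamore maple (*Acer pseudoplatanus*) toxins in
ruminal fluid batch cultures.

Seeds and seedlings of the sycamore maple carry hypoglycin A (HGA), its
γ-glutamyl dipeptide hypoglycin B (HGB), and methylene cyclopropyl glycine
(MCPrG) — the toxins behind atypical myopathy in horses. When maple
material is incubated in closed fermenters with buffered ruminal fluid,
HGB is hydrolysed to HGA while HGA itself is progressively cleared.
`rumentox` is for researchers quantifying that process in vitro: it fits
the compartmental toxin kinetics, processes and models the cumulative
gas-production readout of microbial activity, summarises fermentation
metabolites, and computes the correlation tables used to ask whether the
toxins affect the microbes at all.

## The models

**Conversion–clearance kinetics.** HGA and HGB concentrations follow the
coupled first-order system

```
yHGB'(t) = -k yHGB(t)
yHGA'(t) =  k yHGB(t) - l yHGA(t)
```

with hydrolysis rate `k` (1/h), clearance rate `l` (1/h) and measured
initial values; the package evaluates the closed-form (Bateman) solution
with a numerically safe confluent branch at `l = k`, computes the HGA peak
time in closed form, fits all four parameters `(HGA0, HGB0, k, l)` by
nonlinear least squares on the pooled HGA+HGB series, and cross-checks
everything against a fixed-step Runge–Kutta integration of the same ODEs.
Pure-toxin series (no precursor) are handled by single-exponential decay
with half-life `ln 2 / k`.

**Gas production.** Cumulative head-space pressure is blank-corrected (in
the pressure domain), converted to gas volume via the ideal gas law and
Avogadro's law, downsampled to a 0.5 h grid, normalised per g substrate
dry matter, and fitted with a Gompertz curve in interpretable parameters:
asymptote `a` (mL/g DM), time `b` to one third of `a`, and increment `c`
from `b` to 70% of `a`.

**Fermentation statistics.** NH₃ as test-minus-blank difference,
per-fermenter acetate:propionate (C2:C3) ratios, and Pearson / Spearman /
Kendall tau-b correlation tables at a chosen time point (24 h by default).

**Synthetic experiments.** `experiment_config()` + `generate_experiment()`
reproduce the full study design (4 runs, duplicate fermenters, sampling at
0/1/2/4/8/24/48 h, CSM/PCM/SMS variants, autoclaved controls, censoring at
the limit of quantification) with documented default truth, so the whole
pipeline is testable end to end without laboratory data.

## Worked example

```r
library(rumentox)

cfg <- experiment_config()            # the default study conditions
res <- run_pipeline(cfg, seed = 1)    # simulate + all analysis stages

str(res$kinetics$sms_conversion$parameters)
#> List of 4
#>  $ hga0: num 4.58
#>  $ hgb0: num 21.6
#>  $ k   : num 0.0976
#>  $ l   : num 0.0399
res$kinetics$sms_conversion$hga_peak_time_h
#> [1] 13.4604
```

The seed-incubation fit recovers the generating kinetics (truth:
`HGA0 = 4.7`, `HGB0 = 19.9` µg/mL, `k = 0.093`, `l = 0.039` 1/h) from
noisy, censored data, and predicts the HGA maximum at about 13.5 h of
incubation. The pure-toxin half-lives and per-variant gas kinetics come
out alongside:

```r
res$kinetics$pcm_hga_decay$half_life_h
#> [1] 2.09321
round(sapply(res$gas, function(g) unlist(g$parameters)), 1)
#>     CSM   PCM   SMS
#> a 199.4 271.1 442.5
#> b  18.8  17.7  43.1
#> c   8.5  10.7  31.6
```

i.e. an HGA half-life near the generating 2.05 h, and gas asymptotes /
timing close to the generating truth (200/272/453 mL per g DM) — the seed
variant produces the most gas, the latest, because the seeds are extra
substrate. Correlations at 24 h (here Kendall's tau-b against acetic
acid in the seed incubations):

```r
dplyr::filter(res$correlations$SMS, method == "kendall",
              var1 %in% c("HGA", "HGB"), var2 == "acetic")
#>    method var1   var2       r      p n
#> 1 kendall  HGA acetic  0.5714 0.0478 8
#> 2 kendall  HGB acetic -0.0714 0.8046 8
```

Rising HGA tracks accumulating acetate positively — both are driven by
ongoing fermentation time, not by a toxin effect on the microbes.

See the vignette in `vignettes/maple-toxin-kinetics.Rmd` for the models,
assumptions, parameter defaults and their provenance, and the limits of
what synthetic data can validate.

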