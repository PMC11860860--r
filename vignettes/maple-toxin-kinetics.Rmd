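---
title: "Modelling sycamore maple toxin kinetics in ruminal fluid batch cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sycamore maple toxin kinetics in ruminal fluid batch cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumentox)
library(dplyr)
```

## The scientific problem

Seeds and seedlings of the sycamore maple (*Acer pseudoplatanus*) carry the
protoxins hypoglycin A (HGA), its γ-glutamyl dipeptide hypoglycin B (HGB),
and methylene cyclopropyl glycine (MCPrG). Ingestion causes atypical
myopathy in horses, while ruminants appear less susceptible — raising the
question of what happens to these toxins in ruminal fluid. In a closed
(batch-culture) fermenter inoculated with buffered ruminal fluid, two
processes dominate: hydrolysis of HGB releases HGA, and HGA itself is
progressively transformed, bound or degraded. `rumentox` packages the
quantitative analysis of such experiments: compartmental toxin kinetics,
gas-production kinetics as a readout of microbial activity, metabolite
summaries, and rank/linear correlation tables — together with a
synthetic-data generator that emulates the whole experiment so every stage
is testable without laboratory data.

## The conversion–clearance model

Let $y_{HGB}(t)$ and $y_{HGA}(t)$ be the concentrations of the two toxins.
The model is a pair of coupled first-order compartments,

$$y_{HGB}'(t) = -k\,y_{HGB}(t), \qquad
  y_{HGA}'(t) = k\,y_{HGB}(t) - l\,y_{HGA}(t),$$

with hydrolysis rate $k > 0$ (1/h) and clearance rate $l \ge 0$ (1/h), and
measured initial values $HGA_0$, $HGB_0$. This initial value problem has
the classical precursor–product (Bateman) solution for $l \ne k$:

$$y_{HGB}(t) = HGB_0\,e^{-kt}, \qquad
  y_{HGA}(t) = \tfrac{k}{l-k} HGB_0\, e^{-kt}
  + \Big(HGA_0 - \tfrac{k}{l-k}HGB_0\Big)e^{-lt}.$$

Two numerical choices matter here:

* **Confluent branch.** The two-exponential form suffers catastrophic
  cancellation as $l \to k$. When $|l-k|/\max(k,l) < 10^{-8}$ the package
  evaluates the analytic limit $(HGA_0 + k\,HGB_0\,t)\,e^{-kt}$ instead, so
  `hga_at()` is continuous in the rate constants across the $l=k$ boundary
  (tested to $10^{-6}$ relative).
* **Independent oracle.** `simulate_toxin_ode()` integrates the same system
  with fixed-step fourth-order Runge–Kutta (step $10^{-3}$ h via
  `deSolve::rk4`), providing a route to the solution that shares no code
  with the closed form; the two agree to better than $10^{-5}$ relative
  over 0–48 h on randomized parameter sets.

The HGA maximum, when an interior one exists, is available in closed form
(`hga_peak_time()`); it is cross-checked against a dense grid search to
$10^{-3}$ h. With no precursor, or with clearance already dominating at
$t=0$ ($k\,HGB_0 \le l\,HGA_0$), the curve is non-increasing and `NA` is
returned — a value, not an error, because downstream tabulation must
distinguish "no peak" from "failed".

## Fitting

`fit_conversion_model()` estimates $(HGA_0, HGB_0, k, l)$ by
Levenberg–Marquardt least squares (`minpack.lm`) on the *stacked* HGA and
HGB residuals, unweighted in raw concentration units — the ordinary
least-squares reading of "nonlinear regression" for this design. Both
fitting modes of the original analysis are available: all individual
measurements (default) or per-time-point means (`mode = "means"`).

Starting values are deterministic: initial concentrations from the $t=0$
observations, $k$ from the endpoint log-slope of HGB, $l$ from the
post-peak log-slope of HGA; ten seeded multistarts perturb that guess
uniformly within ±50% and the lowest residual sum of squares wins. Wald
95% intervals come from the Jacobian at the optimum with a $t$ quantile on
$n-p$ degrees of freedom; RMSE uses the residual-df convention
$\sqrt{SSR/(n-p)}$. Censored observations (below the measurement range)
carry their reporting limit and are dropped from the objective by default
(`censored = "half_limit"` substitutes limit/2). Degenerate designs — HGB
identically zero (then $k$ is unidentifiable), fewer than four usable time
points, all-censored series — return a `rumen_fit` with
`converged = FALSE` and a reason, never an exception mid-pipeline.

`fit_exponential_decay()` handles the pure-toxin incubations,
$C(t) = C_0 e^{-kt}$, and reports the half-life $\ln 2/k$ (an exact
identity of the returned object). Non-decaying data yield $k \le 0$ and an
invalid-fit flag.

A seeded calibration experiment, `recovery_study()`, regenerates the
4-runs × 2-duplicates design at 10% observation CV and refits it many
times; across 200 repetitions the Wald intervals for $k$ and $l$ cover the
generating values in well over 90% of replicates, which is what licenses
the interval method under these study conditions.

## Gas production

Cumulative head-space pressure (psi, recorded at a native 5-min interval)
is converted to gas volume through the ideal gas law,
$n = P V_{head}/(RT)$, with one mole occupying 22,414 mL by Avogadro's law
— i.e. volumes are reported at STP by default; `reference = "incubation"`
reports them at 39 °C instead, since the original reporting basis is not
stated. Blank correction happens in the *pressure* domain (mean blank
curve subtracted pointwise, interpolating misaligned grids, negative
results preserved) before conversion and dry-matter normalisation;
`downsample_curve()` then thins the series to a 0.5 h analysis grid by
keeping the last observation at or before each grid point.

The kinetic model is a Gompertz curve in interpretable parameters:
$a$ (asymptotic gas production, mL/g DM), $b$ (hours to $a/3$) and $c$
(additional hours from $b$ to $0.70a$). The exact algebraic form of this
re-parameterization is not reprinted in the source literature, so the
package *defines* the curve by those two constraints on the standard
Gompertz $G(t) = a\exp(-\exp(-(t-m)/s))$, which have the unique solution

$$s = \frac{c}{\ln\!\big(\ln 3 / \ln\tfrac{10}{7}\big)}, \qquad
  m = b + s \ln\ln 3 .$$

The constraints themselves — $G(b) = a/3$, $G(b+c) = 0.7a$ — are what the
tests assert (to $10^{-9}$ relative on randomized parameters), so any
algebraically equivalent published form would pass. `fit_gompertz()`
refits published parameter sets from dense noise-free samplings to better
than $10^{-3}$ relative, and refits at 2% multiplicative noise retain
$R^2 > 0.99$, matching the fit quality reported for the real curves.

One weighting subtlety: ordinary least squares assumes additive
(homoscedastic) error. Under *proportional* measurement error the
asymptote's unweighted Wald interval undercovers (about 86% at 2% CV in
our simulations, against the nominal 95%), because the plateau — which
carries all the information about $a$ — also carries the largest error
variance. `fit_gompertz(weights = "proportional")` scales residuals by the
predicted value and restores nominal coverage under that error model; the
default stays unweighted, matching the additive pressure noise of the
recording hardware. RMSE and $R^2$ are always reported in raw volume
units.

## Metabolites and correlations

NH₃ is reported as test minus mean-blank difference (negative values mean
net nitrogen incorporation into microbial protein). The acetate:propionate
(C2:C3) ratio is computed per fermenter *before* any averaging — the
printed group means of the original tables are only consistent with that
order of operations. `correlation_matrix()` computes Pearson (exact t
test), Spearman (Pearson on average ranks, t-approximation p), and
Kendall's tau-b (tie-corrected, normal-approximation p) at a single time
point, 24 h by default because toxin levels beyond 24 h were sometimes
below the measurement range; the time point is a parameter, not a
constant. Duplicate fermenters produce ties, hence tau-b. Significance
stars follow the conventional 0.05/0.01/0.001 thresholds with no
multiplicity correction, mirroring how such tables are presented.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults *are* the study
conditions:

| quantity | default | origin |
|---|---|---|
| design | 4 runs × 2 duplicates, 0/1/2/4/8/24/48 h | study design |
| SMS initials (µg/mL) | HGA 4.7 ± 1.4, HGB 19.9 ± 5.41, MCPrG 1.2 ± 0.33 | reported 0 h values |
| PCM initials (ng/mL) | HGA 564 ± 133, MCPrG 432 ± 85.1 | reported 0 h values |
| PCM decay | $t_{1/2}$ = 2.05 h (HGA), 2.20 h (MCPrG) | reported half-lives |
| SMS conversion | $k$ = 0.093/h, $l$ = 0.039/h | calibrated, see below |
| gas truth | (a, b, c) = (200, 18.6, 8.5), (272, 17.5, 10.7), (453, 43.5, 32.1) | published fits |
| censoring limit | 0.5 ng/mL | lowest calibration level |
| autoclaved attenuation | 0.25 × on all rates | chosen (see below) |

Choices the source values do not pin down, made once and documented here:

* **SMS rate constants.** No conversion or clearance rate is printed. The
  defaults are the unique $(k, l)$ for which the default initial values
  give an HGA peak at 13.7 h and a 48 h HGA residual of 5.6 µg/mL — the
  two facts that *are* printed. (Solved numerically once; the defaults are
  the rounded solution.)
* **Noise families.** Multiplicative lognormal with unit mean for
  concentrations (non-negative support; CV per analyte from the printed
  SD/mean at 0 h, held constant over time because time-resolved SDs exist
  only in figures), additive Gaussian for pH/redox/metabolites (SDs taken
  from the printed standard errors). Only means ± dispersions are
  reported, so the families are modelling choices.
* **Autoclaved attenuation 0.25×.** Transformation also occurred in
  autoclaved (abiotic) medium but "not as strong"; no rate is printed, so
  the factor is configurable with a conservative default.
* **Between-run variance.** Not recoverable from printed values; a single
  pooled CV is the default, with an optional run-level lognormal
  multiplier (`run_cv_multiplier`, default 0, no literature-derived
  value).
* **Gas background.** Blanks contribute a slow linear pressure drift
  (0.02 psi/h) plus measurement noise; recordings are kept cumulative
  (clamped non-negative, non-decreasing), as pressure modules report them.
  Valve-release events (1.5 psi threshold) are hardware behaviour and are
  not simulated.
* **Longitudinal simplification.** The real protocol removes two
  fermenters per sampling time; the generator follows each duplicate
  fermenter across the whole grid. For the pooled regressions performed
  here the two designs are statistically equivalent; analyses sensitive to
  repeated-measures structure should not rely on the generator.
* **Metabolite trajectories** interpolate each variant's 0 h and 48 h
  anchors along the variant's normalised Gompertz shape — fermentation
  products accumulate as fermentation gas does. This is a smoothness
  assumption; the real interior time courses were not published.

Determinism: every fermenter draws from its own substream whose seed is a
fixed function of (seed, run, variant, medium, duplicate), so regenerating
with the same configuration and seed is bit-identical, and subsetting runs
does not shift other runs' draws.

What passing tests on synthetic data do **not** show: the generator cannot
validate the model *form* against reality (its toxin curves are drawn from
the very models being fitted), nor matrix effects, adsorption, microbial
adaptation, or the true between-run variance structure. It validates the
numerics — that the estimators recover known truth under realistic noise,
censoring and design.

## Problem sizes used in the test suite

The suite exercises: 100 random parameter sets for the closed-form vs
Runge–Kutta equivalence (grid 0–48 h), 200 seeded repetitions of the
4 × 2 × 7 recovery design at 10% CV for interval coverage, 500 fermenters
for the 0 h draw fidelity check, and dense 0.5 h samplings over 0–48 h
(0–96 h for the slow seed variant) for the Gompertz round trips. These
sizes were chosen to estimate each property with comfortable margin while
keeping the default test run short.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
cfg <- experiment_config()
res <- run_pipeline(cfg, seed = 1, out_dir = "reports")

# conversion-clearance fit of the seed incubations, with the predicted
# HGA peak time
res$kinetics$sms_conversion$parameters
res$kinetics$sms_conversion$hga_peak_time_h

# pure-toxin half-lives
res$kinetics$pcm_hga_decay$half_life_h

# per-variant Gompertz parameters from blank-corrected, downsampled,
# DM-normalised volumes
sapply(res$gas, function(g) unlist(g$parameters))

# correlation table at 24 h
res$correlations$SMS |> dplyr::filter(method == "kendall")
```

## Known limitations

* Single-curve fits only: no hierarchical (random-effects-by-run)
  extension, matching the original pooled analysis.
* No mechanistic model of downstream toxin metabolites (none were detected
  in the source system) and no adsorption/binding sub-model.
* Wald intervals are asymptotic; for the slow seed-variant gas curve the
  asymptote is an extrapolation and its interval is wide — the fit reports
  this honestly rather than constraining it.
* The least-squares-means mixed model for the metabolite tables is
  deliberately out of scope; `nh3_difference()` and `c2_c3_ratio()`
  prepare the data, and standard mixed-model software applies from there.
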