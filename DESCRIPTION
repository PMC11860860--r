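Package: rumentox
Title: Kinetics of Sycamore Maple Toxins in Ruminal Fluid Batch Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the fate of the sycamore maple (Acer pseudoplatanus)
    toxins hypoglycin A (HGA), hypoglycin B (HGB) and methylene cyclopropyl
    glycine (MCPrG) in in vitro ruminal fluid batch cultures. Implements a
    two-compartment first-order conversion-clearance model for the release
    of HGA from HGB, single-exponential decay and half-life estimation for
    pure toxins, a re-parameterized Gompertz model for cumulative gas
    production with pressure-to-volume conversion and blank correction,
    fermentation-metabolite summaries (NH3 net difference, acetate to
    propionate ratio) and rank/linear correlation tables. A deterministic
    synthetic-data generator emulates the full batch-culture experiment so
    every pipeline stage can be exercised and validated without access to
    raw laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    deSolve,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
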