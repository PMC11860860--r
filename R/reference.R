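#' Published reference values for the batch-culture study conditions
#'
#' `reference_gas_kinetics()` returns the published Gompertz gas-production
#' estimates for the three incubated variants: the cellulose-starch control
#' substrate (CSM), CSM plus a pure HGA/MCPrG mixture (PCM), and CSM plus
#' milled sycamore maple seeds (SMS). `reference_toxin_initials()` returns
#' the reported initial (and where available, final) toxin concentrations
#' per variant and medium. These constants parameterise the synthetic-data
#' generator's default study conditions and the self-consistency checks of
#' the Gompertz parameterization.
#'
#' @return A tibble; see the column comments in the source.
#' @export
reference_gas_kinetics <- function() {
  tibble(
    variant = c("CSM", "PCM", "SMS"),
    a = c(200, 272, 453),      # asymptotic gas production, mL/g DM
    b = c(18.6, 17.5, 43.5),   # h to one third of a
    c = c(8.5, 10.7, 32.1)     # additional h from b to 70% of a
  )
}

#' @rdname reference_gas_kinetics
#' @export
reference_toxin_initials <- function() {
  tibble(
    variant = c("PCM", "PCM", "PCM", "PCM",
                "SMS", "SMS", "SMS", "SMS", "SMS", "SMS"),
    medium  = c("vital", "vital", "autoclaved", "autoclaved",
                "vital", "vital", "vital",
                "autoclaved", "autoclaved", "autoclaved"),
    analyte = c("HGA", "MCPrG", "HGA", "MCPrG",
                "HGA", "HGB", "MCPrG", "HGA", "HGB", "MCPrG"),
    c0      = c(564, 432, 587, 326,
                4.7, 19.9, 1.2, 1.4, 21.1, 0.64),
    c0_sd   = c(133, 85.1, 198, 74.3,
                1.4, 5.41, 0.33, 0.64, 11.0, 0.24),
    unit    = c(rep("ng/mL", 4), rep("ug/mL", 6))
  )
}

#' @rdname reference_gas_kinetics
#' @return `reference_metabolite_anchors()`: per-variant 0 h and 48 h
#'   least-squares-mean anchors (with standard errors) for pH, redox
#'   potential (mV), the SCFAs (mmol/L) and the NH3 net difference
#'   (mmol/L), used as endpoint anchors by the metabolite generator.
#' @export
reference_metabolite_anchors <- function() {
  # columns: variant, analyte, v0 (0 h), v48 (48 h), se
  tribble_anchor <- function(variant, analyte, v0, v48, se)
    tibble(variant = variant, analyte = analyte, v0 = v0, v48 = v48, se = se)
  bind_rows(
    tribble_anchor("CSM", "pH", 7.0, 6.8, 0.14),
    tribble_anchor("CSM", "redox", -178, -215, 34.2),
    tribble_anchor("CSM", "acetic", 18, 41, 8.5),
    tribble_anchor("CSM", "propionic", 6.8, 22, 2.7),
    tribble_anchor("CSM", "n-butyric", 1.7, 4.5, 1.1),
    tribble_anchor("CSM", "iso-butyric", 0.42, 0.75, 0.18),
    tribble_anchor("CSM", "n-valeric", 0.14, 0.35, 0.061),
    tribble_anchor("CSM", "iso-valeric", 0.58, 1.1, 0.23),
    tribble_anchor("CSM", "NH3", -1.2, -5.7, 1.2),
    tribble_anchor("PCM", "pH", 6.9, 6.6, 0.024),
    tribble_anchor("PCM", "redox", -189, -249, 22.5),
    tribble_anchor("PCM", "acetic", 22, 48, 1.2),
    tribble_anchor("PCM", "propionic", 4.3, 24, 0.88),
    tribble_anchor("PCM", "n-butyric", 2.1, 4.9, 0.50),
    tribble_anchor("PCM", "iso-butyric", 0.20, 0.60, 0.046),
    tribble_anchor("PCM", "n-valeric", 0.14, 0.38, 0.023),
    tribble_anchor("PCM", "iso-valeric", 0.30, 0.91, 0.069),
    tribble_anchor("PCM", "NH3", -1.8, -5.3, 0.41),
    tribble_anchor("SMS", "pH", 6.9, 6.7, 0.051),
    tribble_anchor("SMS", "redox", -184, -280, 16.6),
    tribble_anchor("SMS", "acetic", 22, 64, 2.8),
    tribble_anchor("SMS", "propionic", 4.5, 11, 0.61),
    tribble_anchor("SMS", "n-butyric", 2.9, 6.3, 0.55),
    tribble_anchor("SMS", "iso-butyric", 0.21, 0.10, 0.013),
    tribble_anchor("SMS", "n-valeric", 0.15, 0.39, 0.030),
    tribble_anchor("SMS", "iso-valeric", 0.32, 0.14, 0.017),
    tribble_anchor("SMS", "NH3", -1.3, -4.8, 0.39)
  )
}
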