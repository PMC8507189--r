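#' Reference phenophase dates for six colour indices
#'
#' Published single-ROI transition days (day of year) from a 14-month
#' deciduous-plantation camera study, one row per colour index: start of
#' season (SOS), maturity onset (MOE), growth-stage length (LOS = MOE - SOS)
#' and end of season (EOS). Useful as a worked example for the LOS identity
#' and for comparing phenophase orderings; the GGR maturity onset, garbled
#' in the original table, is reconstructed from the index's reported LOS.
#'
#' @return Tibble: `index`, `sos`, `moe`, `los`, `eos`.
#' @examples
#' fd <- forest_phenodates()
#' all(fd$los == fd$moe - fd$sos)
#' @export
forest_phenodates <- function() {
  tibble::tribble(
    ~index, ~sos, ~moe, ~los, ~eos,
    "grvi",   91L, 145L, 54L, 337L,
    "ggr",    91L, 132L, 41L, 337L,
    "rcc",    91L, 145L, 54L, 330L,
    "gcc",    67L, 108L, 41L, 337L,
    "hue",    67L, 145L, 78L, 337L,
    "gei",    67L, 108L, 41L, 337L)
}
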