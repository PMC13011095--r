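#' Reference soil survey summary for the two study areas
#'
#' Published summary statistics of an agricultural soil survey around a
#' non-ferrous metal mining and smelting district: per-metal median and
#' interquartile range of the concentration (mg/kg) in an uncontaminated
#' area (UA, 36 sites) and a contaminated area (CA, 44 sites), together
#' with the regional soil background value for each of the eight metals.
#' These summaries are the inputs for median-based contamination factors
#' and for parameterising the synthetic soil-survey generator.
#'
#' @return a data.frame with one row per metal and columns `metal`,
#'   `ua_median`, `ua_q1`, `ua_q3`, `ca_median`, `ca_q1`, `ca_q3`,
#'   `background`.
#' @export
soil_reference <- function() {
  data.frame(
    metal      = c("Mo", "Sb", "Pb", "Mn", "Co", "Cu", "Zn", "Cd"),
    ua_median  = c(0.588, 0.925, 13.613, 398.500, 6.890, 16.811, 53.746, 0.162),
    ua_q1      = c(0.517, 0.836, 12.146, 360.436, 6.220, 12.310, 42.771, 0.146),
    ua_q3      = c(0.678, 1.021, 14.962, 454.033, 8.218, 35.350, 59.167, 0.197),
    ca_median  = c(0.462, 1.547, 70.956, 304.834, 4.759, 34.866, 117.849, 2.944),
    ca_q1      = c(0.378, 0.792, 22.704, 274.220, 4.225, 15.665, 59.154, 0.903),
    ca_q3      = c(0.619, 2.723, 158.576, 344.499, 5.231, 70.749, 462.924, 10.428),
    background = c(0.920, 1.140, 22.900, 694.000, 14.600, 30.500, 72.700, 0.180),
    stringsAsFactors = FALSE
  )
}

#' Regional background values for the eight surveyed heavy metals
#'
#' @return named numeric vector of background concentrations (mg/kg).
#' @export
metal_backgrounds <- function() {
  ref <- soil_reference()
  stats::setNames(ref$background, ref$metal)
}
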