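## Published posterior summaries for the Rubia Gallega beef cattle
## population, kept as plain inputs for arithmetic cross-checks
## (depression percentages, heritability and load-variance ratios).

#' Published trait summaries for the Rubia Gallega population
#'
#' Phenotypic means/SDs and posterior estimates (mean and posterior SD)
#' of the inbreeding-depression regression and variance components
#' reported for seven traits in the Rubia Gallega beef cattle
#' population: birth weight (BW), weaning weight (WW), cold carcass
#' weight (CCW), carcass conformation (CONF), carcass fatness (FAT),
#' calving interval (CI) and age at first parity (AFP).  Units are kg
#' (BW, WW, CCW), score units (CONF, FAT) and days (CI, AFP); variances
#' are in squared trait units.  `NA` marks components absent from a
#' trait's model (the permanent environmental variance exists only for
#' the repeated-records trait CI).
#'
#' These are reported values, not computed by this package; they serve
#' as inputs to [depressionSummary()], [heritability()] and
#' [loadVarianceRatio()] when reproducing the published derived
#' statistics.
#'
#' @return data.frame with one row per trait.
#' @export
referenceEstimates <- function() {
  data.frame(
    trait = c("BW", "WW", "CCW", "CONF", "FAT", "CI", "AFP"),
    mean  = c(42.65, 287.87, 224.58, 10.95, 5.76, 401.42, 865.85),
    sd    = c(7.02, 47.71, 41.23, 1.99, 1.33, 61.74, 136.38),
    d     = c(-1.20, -33.14, -59.29, -0.88, -0.86, 30.24, 74.27),
    dPSD  = c(0.33, 4.97, 3.91, 0.22, 0.14, 6.38, 34.11),
    su2   = c(9.27, 450.64, 476.50, 1.43, 0.58, 199.36, 4298.96),
    si2   = c(57.97, 1907.93, 7965.10, 25.61, 10.78, 7356.46, 194546.51),
    sui   = c(-11.03, -547.68, -847.18, -3.26, -1.85, -460.15, -12964.96),
    sh2   = c(7.89, 251.86, 302.00, 0.27, 0.10, 264.29, 2414.99),
    sp2   = c(NA, NA, NA, NA, NA, 208.33, NA),
    se2   = c(29.49, 980.22, 456.65, 1.59, 1.01, 3080.66, 11985.86),
    stringsAsFactors = FALSE
  )
}
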