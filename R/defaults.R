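# Package-level calibrated defaults.
#
# track_bias_*: shared migration bias of the synthetic cohort generator,
#   tuned once (Monte Carlo root-finding at large n) so the seed-averaged
#   mean per-cell maximum displacement over the 16-hr window matches the
#   spheroid tracking study statistics (111.11 um GFP-like, 68.34 um DsRed-like).
# uptake_viable: per-cell oxygen uptake rate (1/min), tuned once so the
#   steady radial profile of a mature simulated tumor reads ~6 mmHg at the
#   viable/necrotic interface with a 45 mmHg far-field.
.hypoxfate_defaults <- new.env(parent = emptyenv())
.hypoxfate_defaults$track_bias_gfp <- 0.35163
.hypoxfate_defaults$track_bias_dsred <- 0.30436
.hypoxfate_defaults$uptake_viable <- 5.5
.hypoxfate_defaults$uptake_necrotic_frac <- 0.1

#' Calibrated package defaults
#'
#' Returns the package's tuned default constants: the synthetic-cohort
#' generator biases and the per-cell oxygen uptake rate.
#'
#' @return a named list
#' @export
hypoxfate_defaults <- function() {
  as.list(.hypoxfate_defaults)
}
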