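# Physical constants (CODATA 2018) in the unit system used throughout:
# s in inverse Angstrom, r in Angstrom, f in Angstrom, energies in MeV,
# wavelengths in pm unless stated otherwise.

#' Physical constants used by lued
#'
#' A named list of the CODATA constants the package relies on:
#' `mec2_mev` (electron rest energy, MeV), `hc_mev_pm` (h*c, MeV pm),
#' `c_um_per_fs` (speed of light, micrometres per femtosecond).
#'
#' @export
lued_constants <- list(
  mec2_mev    = 0.51099895,
  hc_mev_pm   = 1.23984198,
  c_um_per_fs = 0.299792458
)

# internal shorthands
.MEC2 <- lued_constants$mec2_mev
.HC_MEV_PM <- lued_constants$hc_mev_pm
.C_UM_FS <- lued_constants$c_um_per_fs

.stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
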