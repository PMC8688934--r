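# Physical constants (CODATA) and fixed model conventions.
# Internal unit system: SI with concentrations in mol/m^3 (numerically equal to mM),
# volumes in m^3, amounts in mol, time in s, potentials in V at the kinetic core
# (user-facing interfaces take mV). Temperature is fixed at 310.15 K.

.FARADAY  <- 96485.33212      # C/mol
.RGAS     <- 8.314462618      # J/(mol K)
.TEMP     <- 310.15           # K
.RT_F     <- .RGAS * .TEMP / .FARADAY   # ~0.026712 V
.AVOGADRO <- 6.02214076e23

#' Thermal voltage RT/F at the model temperature
#'
#' @return RT/F in volts at 310.15 K.
#' @keywords internal
rt_over_f <- function() .RT_F

#' Convert millivolts to volts
#' @param mv potential in mV.
#' @keywords internal
mv_to_v <- function(mv) mv * 1e-3
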