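#' Full model configuration
#'
#' Assembles the complete parameterisation of the three-compartment
#' enterocyte model: transporter kinetics and copy numbers, channel and water
#' permeabilities per membrane, the impermeant intracellular osmolyte pool,
#' the perfused blood compartment, and the bath compositions.
#'
#' @param sglt1 an [sglt1_params()] (apical membrane).
#' @param glut2_apical,glut2_basolateral [carrier_params()] objects. The
#'   baseline copy numbers are 1e8 apical and 2e8 basolateral GLUT2 with
#'   3e7 SGLT1.
#' @param pump a [pump_params()] (basolateral membrane).
#' @param channels named list of [channel_params()]; defaults provide Na+, K+
#'   and Cl- conductances on the apical and basolateral membranes and a
#'   paracellular shunt.
#' @param water named list of [water_params()] for the apical, basolateral and
#'   paracellular water pathways.
#' @param osmolytes list with `amount` (mol of impermeant intracellular
#'   osmolytes) and `valence` (mean valence, dimensionless).
#' @param blood_volume fixed blood-compartment volume (m^3); baseline 1e-16.
#' @param blood_flow constant inlet blood flow (m^3/s); baseline 1e-17.
#' @param blood_inflow named list: composition of the inflowing blood (mM and
#'   pH).
#' @param lumen named list: luminal bath composition (mM and pH). The lumen is
#'   an infinite bath of constant composition unless `lumen_finite`.
#' @param cells_per_cm linear cell density used when reporting fluxes per cm
#'   of intestine (cm^-1); default derived from the published segment cell
#'   count (1.3e9 cells per 75 cm loop).
#' @param lumen_finite logical; if `TRUE` the lumen is a closed finite
#'   compartment of volume `lumen_volume` whose composition evolves (used for
#'   conservation checks, not a physiological scenario).
#' @param lumen_volume lumen volume (m^3) when `lumen_finite`.
#'
#' @return Object of class `model_config`.
#' @examples
#' cfg <- model_config()
#' cfg$blood_flow
#' @export
model_config <- function(sglt1 = sglt1_params(n_copies = 3e7),
                         glut2_apical = carrier_params(n_copies = 1e8),
                         glut2_basolateral = glut2_basolateral_params(),
                         pump = pump_params(),
                         channels = default_channels(),
                         water = default_water_pathways(),
                         osmolytes = list(amount = .CELL_DEFAULT$osmolyte_amount,
                                          valence = .CELL_DEFAULT$osmolyte_valence),
                         blood_volume = 1e-16,
                         blood_flow = 1e-17,
                         blood_inflow = list(na = 150, k = 5, cl = 150,
                                             hco3 = 0, glucose = 4, ph = 7.4),
                         lumen = list(na = 150, k = 5, cl = 150,
                                      hco3 = 0, glucose = 0, ph = 7.4),
                         cells_per_cm = 1.3e9 / 75,
                         lumen_finite = FALSE,
                         lumen_volume = 1e-14) {
  stopifnot(inherits(sglt1, "sglt1_params"),
            inherits(glut2_apical, "carrier_params"),
            inherits(glut2_basolateral, "carrier_params"),
            inherits(pump, "pump_params"))
  if (!is.finite(blood_volume) || blood_volume <= 0)
    stop("model_config: blood_volume must be > 0", call. = FALSE)
  if (!is.finite(blood_flow) || blood_flow < 0)
    stop("model_config: blood_flow must be >= 0", call. = FALSE)
  for (ch in channels) stopifnot(inherits(ch, "channel_params"))
  for (w in water) stopifnot(inherits(w, "water_params"))
  if (!is.finite(osmolytes$amount) || osmolytes$amount < 0)
    stop("model_config: osmolyte amount must be >= 0", call. = FALSE)
  structure(list(sglt1 = sglt1,
                 glut2_apical = glut2_apical,
                 glut2_basolateral = glut2_basolateral,
                 pump = pump,
                 channels = channels,
                 water = water,
                 osmolytes = osmolytes,
                 blood_volume = blood_volume,
                 blood_flow = blood_flow,
                 blood_inflow = blood_inflow,
                 lumen = lumen,
                 cells_per_cm = cells_per_cm,
                 lumen_finite = lumen_finite,
                 lumen_volume = lumen_volume),
            class = "model_config")
}

#' Baseline channel set
#'
#' Na+, K+ and Cl- GHK conductances on both cell membranes plus a
#' cation-selective paracellular shunt. Permeability-area products are the
#' calibrated baseline values.
#' @return Named list of [channel_params()].
#' @export
default_channels <- function() {
  d <- .CELL_DEFAULT
  list(
    ap_na = channel_params(d$p_ap_na, +1, "apical"),
    ap_k  = channel_params(d$p_ap_k,  +1, "apical"),
    ap_cl = channel_params(d$p_ap_cl, -1, "apical"),
    bl_na = channel_params(d$p_bl_na, +1, "basolateral"),
    bl_k  = channel_params(d$p_bl_k,  +1, "basolateral"),
    bl_cl = channel_params(d$p_bl_cl, -1, "basolateral"),
    pc_na = channel_params(d$p_pc_na, +1, "paracellular"),
    pc_k  = channel_params(d$p_pc_k,  +1, "paracellular"),
    pc_cl = channel_params(d$p_pc_cl, -1, "paracellular")
  )
}

#' Baseline water pathways
#' @return Named list of [water_params()] (apical, basolateral, paracellular).
#' @export
default_water_pathways <- function() {
  d <- .CELL_DEFAULT
  list(
    apical       = water_params(d$lp_ap, "apical"),
    basolateral  = water_params(d$lp_bl, "basolateral"),
    paracellular = water_params(d$lp_pc, "paracellular")
  )
}

#' Convenience modifiers for scenario construction
#'
#' `set_luminal_glucose()` returns the configuration with the luminal glucose
#' bath changed; `without_apical_glut2()` removes apical GLUT2;
#' `scale_copies()` multiplies the copy number of one transporter.
#'
#' @param config a [model_config()].
#' @param glucose luminal glucose (mM).
#' @return Modified `model_config`.
#' @export
set_luminal_glucose <- function(config, glucose) {
  stopifnot(glucose >= 0)
  config$lumen$glucose <- glucose
  config
}

#' @rdname set_luminal_glucose
#' @export
without_apical_glut2 <- function(config) {
  config$glut2_apical$n_copies <- 0
  config
}

#' @rdname set_luminal_glucose
#' @param transporter one of `"sglt1"`, `"glut2_apical"`, `"glut2_basolateral"`.
#' @param factor multiplicative factor (>= 0) applied to the copy number.
#' @export
scale_copies <- function(config, transporter = c("sglt1", "glut2_apical",
                                                 "glut2_basolateral"),
                         factor) {
  transporter <- match.arg(transporter)
  stopifnot(factor >= 0)
  config[[transporter]]$n_copies <- config[[transporter]]$n_copies * factor
  config
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  SGLT1 %.3g | apical GLUT2 %.3g | basolateral GLUT2 %.3g copies\n",
              x$sglt1$n_copies, x$glut2_apical$n_copies,
              x$glut2_basolateral$n_copies))
  cat(sprintf("  blood: V %.3g m^3, inlet flow %.3g m^3/s, inflow glucose %g mM\n",
              x$blood_volume, x$blood_flow, x$blood_inflow$glucose))
  cat(sprintf("  lumen: Na %g K %g Cl %g glucose %g mM%s\n",
              x$lumen$na, x$lumen$k, x$lumen$cl, x$lumen$glucose,
              if (x$lumen_finite) " (finite, closed)" else " (infinite bath)"))
  invisible(x)
}
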