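#' Compartment state
#'
#' Container for the composition and volume of one model compartment
#' (intestinal lumen, enterocyte cytosol, or the perfused blood compartment).
#' Concentrations are in mM (numerically mol/m^3), volume in m^3.
#'
#' @param na,k,cl,hco3,glucose solute concentrations (mM). Must be >= 0.
#' @param ph compartment pH (dimensionless).
#' @param volume compartment volume (m^3). Must be > 0.
#' @param role one of `"lumen"`, `"cell"`, `"blood"`.
#'
#' @details The lumen is treated as an infinite bath of fixed composition
#'   during a simulation; the blood compartment has a finite, fixed volume and
#'   variable composition; the cell has variable composition and volume.
#'
#' @return An object of class `compartment_state`.
#' @examples
#' lum <- compartment_state(na = 150, k = 5, cl = 150, glucose = 50,
#'                          volume = 1e-12, role = "lumen")
#' compute_osmolarity(lum)
#' @export
compartment_state <- function(na, k, cl, hco3 = 0, glucose = 0, ph = 7.4,
                              volume = 1e-15,
                              role = c("cell", "lumen", "blood")) {
  role <- match.arg(role)
  conc <- c(na = na, k = k, cl = cl, hco3 = hco3, glucose = glucose)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("compartment_state: concentrations must be finite and >= 0", call. = FALSE)
  if (!is.finite(volume) || volume <= 0)
    stop("compartment_state: volume must be > 0", call. = FALSE)
  structure(list(na = na, k = k, cl = cl, hco3 = hco3, glucose = glucose,
                 ph = ph, volume = volume, role = role),
            class = "compartment_state")
}

#' @export
print.compartment_state <- function(x, ...) {
  cat(sprintf("<compartment_state: %s>\n", x$role))
  cat(sprintf("  Na+ %.3g  K+ %.3g  Cl- %.3g  HCO3- %.3g  glucose %.4g mM\n",
              x$na, x$k, x$cl, x$hco3, x$glucose))
  cat(sprintf("  pH %.3f   volume %.4g m^3\n", x$ph, x$volume))
  invisible(x)
}

# Species valences used in charge bookkeeping (H+ is carried implicitly via pH
# and contributes negligibly to charge and osmolarity).
.ION_VALENCE <- c(na = +1, k = +1, cl = -1, hco3 = -1, glucose = 0)

#' Osmolarity of a compartment
#'
#' Sum of all solute concentrations with an ideal osmotic coefficient of 1.
#' For the cell this includes the impermeant intracellular osmolytes declared
#' in the model configuration (amount / current volume).
#'
#' @param state a [compartment_state()].
#' @param config optional [model_config()]; required to count the impermeant
#'   osmolyte pool of the cell compartment.
#' @return Osmolarity in mOsm (mol/m^3).
#' @export
compute_osmolarity <- function(state, config = NULL) {
  osm <- state$na + state$k + state$cl + state$hco3 + state$glucose
  if (identical(state$role, "cell") && !is.null(config))
    osm <- osm + config$osmolytes$amount / state$volume
  osm
}

#' Net charge concentration of a compartment (mM of elementary charge)
#'
#' @inheritParams compute_osmolarity
#' @return Signed charge concentration in mM; for the cell this includes the
#'   impermeant osmolytes at their mean valence.
#' @keywords internal
charge_concentration <- function(state, config = NULL) {
  q <- state$na + state$k - state$cl - state$hco3
  if (identical(state$role, "cell") && !is.null(config))
    q <- q + config$osmolytes$valence * config$osmolytes$amount / state$volume
  q
}
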