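# Parameter constructors and validators for the transporter kinetic laws.
#
# Rate-constant units: first-order s^-1; substrate-binding steps mM^-1 s^-1
# (sodium binding of SGLT1 is second order in Na+ and carries mM^-2 s^-1).
# Copy numbers are per cell.

#' SGLT1 six-state cycle parameters
#'
#' The sodium-glucose cotransporter is modelled as a single loop of six
#' carrier states: 1 outward-facing empty, 2 outward with 2 Na+ bound,
#' 3 outward fully loaded (2 Na+ + glucose), 4 inward fully loaded,
#' 5 inward with 2 Na+, 6 inward empty.  Forward (clockwise, state 1 -> 2 ->
#' ... -> 6 -> 1) traversal moves one glucose and two Na+ into the cell.
#'
#' @param k12,k21 outer Na+ binding/release (mM^-2 s^-1, s^-1).
#' @param k23,k32 outer glucose binding/release (mM^-1 s^-1, s^-1).
#' @param k34,k43 translocation of the loaded carrier (s^-1).
#' @param k45,k54 inner glucose release/binding (s^-1, mM^-1 s^-1).
#' @param k56,k65 inner Na+ release/binding (s^-1, mM^-2 s^-1).
#' @param k61 return of the empty carrier to the outward face (s^-1).
#' @param k16 reverse of `k61` (s^-1); if `NULL` it is derived from the
#'   thermodynamic cycle condition so that the cycle carries no net flux at
#'   zero voltage and equal bath compositions (detailed balance).
#' @param q12,q34,q61 apparent charges moved into the cell during the forward
#'   transition (dimensionless); symmetric Eyring voltage factors
#'   `exp(-q F V / 2RT)` apply forward and their reciprocal backward. The sum
#'   over the cycle must equal +2 (two Na+ translocated per turn).
#' @param n_copies transporter copies per cell.
#'
#' @return Object of class `sglt1_params`.
#' @export
sglt1_params <- function(k12 = .SGLT1_DEFAULT$k12, k21 = .SGLT1_DEFAULT$k21,
                         k23 = .SGLT1_DEFAULT$k23, k32 = .SGLT1_DEFAULT$k32,
                         k34 = .SGLT1_DEFAULT$k34, k43 = .SGLT1_DEFAULT$k43,
                         k45 = .SGLT1_DEFAULT$k45, k54 = .SGLT1_DEFAULT$k54,
                         k56 = .SGLT1_DEFAULT$k56, k65 = .SGLT1_DEFAULT$k65,
                         k61 = .SGLT1_DEFAULT$k61, k16 = NULL,
                         q12 = 0.6, q34 = 0, q61 = 1.4,
                         n_copies = 3e7) {
  rates <- c(k12 = k12, k21 = k21, k23 = k23, k32 = k32, k34 = k34, k43 = k43,
             k45 = k45, k54 = k54, k56 = k56, k65 = k65, k61 = k61)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("sglt1_params: all rate constants must be finite and > 0", call. = FALSE)
  if (!is.finite(n_copies) || n_copies < 0)
    stop("sglt1_params: n_copies must be >= 0", call. = FALSE)
  qs <- c(q12 = q12, q34 = q34, q61 = q61)
  if (abs(sum(qs) - 2) > 1e-9)
    stop("sglt1_params: apparent charges must sum to +2 per forward cycle",
         call. = FALSE)
  # Detailed balance around the loop (concentration factors cancel pairwise):
  # k12 k23 k34 k45 k56 k61 = k21 k32 k43 k54 k65 k16.
  k16_db <- (k12 * k23 * k34 * k45 * k56 * k61) /
            (k21 * k32 * k43 * k54 * k65)
  if (is.null(k16)) {
    k16 <- k16_db
  } else if (abs(log(k16 / k16_db)) > 1e-6) {
    stop("sglt1_params: supplied k16 violates the thermodynamic cycle condition",
         call. = FALSE)
  }
  structure(list(rates = c(rates, k16 = k16), charges = qs,
                 n_copies = n_copies, stoichiometry = c(na = 2, glucose = 1)),
            class = "sglt1_params")
}

#' Alternating-conformation carrier (GLUT2) parameters
#'
#' Four-state facilitated-diffusion carrier: outward-facing empty, outward
#' loaded, inward loaded, inward empty.  No energy input: net flux vanishes
#' when the two substrate concentrations are equal, which is guaranteed by
#' deriving one rate constant from the thermodynamic cycle condition.
#'
#' @param k_on_out,k_off_out glucose binding/release at the outward face
#'   (mM^-1 s^-1, s^-1).
#' @param k_on_in,k_off_in glucose binding/release at the inward face.
#' @param k_tl_oi,k_tl_io translocation of the loaded carrier out->in / in->out
#'   (s^-1).
#' @param k_mt_io return of the empty carrier in->out (s^-1).
#' @param k_mt_oi reverse of `k_mt_io`; derived from detailed balance if `NULL`.
#' @param n_copies carrier copies per cell.
#' @return Object of class `carrier_params`.
#' @export
carrier_params <- function(k_on_out = .GLUT2_DEFAULT$k_on_out,
                           k_off_out = .GLUT2_DEFAULT$k_off_out,
                           k_on_in = .GLUT2_DEFAULT$k_on_in,
                           k_off_in = .GLUT2_DEFAULT$k_off_in,
                           k_tl_oi = .GLUT2_DEFAULT$k_tl_oi,
                           k_tl_io = .GLUT2_DEFAULT$k_tl_io,
                           k_mt_io = .GLUT2_DEFAULT$k_mt_io,
                           k_mt_oi = NULL,
                           n_copies = 2e8) {
  rates <- c(k_on_out = k_on_out, k_off_out = k_off_out,
             k_on_in = k_on_in, k_off_in = k_off_in,
             k_tl_oi = k_tl_oi, k_tl_io = k_tl_io, k_mt_io = k_mt_io)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("carrier_params: all rate constants must be finite and > 0", call. = FALSE)
  if (!is.finite(n_copies) || n_copies < 0)
    stop("carrier_params: n_copies must be >= 0", call. = FALSE)
  # Detailed balance: on_out * tl_oi * off_in * mt_io = off_out * tl_io * on_in * mt_oi
  k_mt_oi_db <- (k_on_out * k_tl_oi * k_off_in * k_mt_io) /
                (k_off_out * k_tl_io * k_on_in)
  if (is.null(k_mt_oi)) {
    k_mt_oi <- k_mt_oi_db
  } else if (abs(log(k_mt_oi / k_mt_oi_db)) > 1e-6) {
    stop("carrier_params: supplied k_mt_oi violates the thermodynamic cycle condition",
         call. = FALSE)
  }
  structure(list(rates = c(rates, k_mt_oi = k_mt_oi), n_copies = n_copies),
            class = "carrier_params")
}

#' Baseline basolateral GLUT2 parameters
#'
#' The basolateral pool shares the apical carrier's cycle topology but turns
#' over more slowly and binds cytosolic glucose with lower affinity; its
#' rates are calibrated against the whole-cell steady-state operating points
#' (see the methods vignette).
#'
#' @param n_copies carrier copies per cell (baseline 2e8).
#' @return A [carrier_params()] object.
#' @export
glut2_basolateral_params <- function(n_copies = 2e8) {
  d <- .GLUT2_BL_DEFAULT
  carrier_params(d$k_on_out, d$k_off_out, d$k_on_in, d$k_off_in,
                 d$k_tl_oi, d$k_tl_io, d$k_mt_io, n_copies = n_copies)
}

#' Na+/K+-ATPase pump parameters
#'
#' Hill-type saturating law with fixed 3 Na+ out : 2 K+ in stoichiometry.
#' The pump runs forward only.
#'
#' @param k_max maximal turnover per pump (cycles/s).
#' @param km_na apparent half-saturation for intracellular Na+ (mM).
#' @param km_k apparent half-saturation for extracellular K+ (mM).
#' @param h_na,h_k Hill exponents (default 3 and 2, matching stoichiometry).
#' @param n_copies pumps per cell.
#' @return Object of class `pump_params`.
#' @export
pump_params <- function(k_max = .PUMP_DEFAULT$k_max,
                        km_na = .PUMP_DEFAULT$km_na,
                        km_k = .PUMP_DEFAULT$km_k,
                        h_na = 3, h_k = 2,
                        n_copies = .PUMP_DEFAULT$n_copies) {
  v <- c(k_max = k_max, km_na = km_na, km_k = km_k, h_na = h_na, h_k = h_k)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("pump_params: all parameters must be finite and > 0", call. = FALSE)
  if (!is.finite(n_copies) || n_copies < 0)
    stop("pump_params: n_copies must be >= 0", call. = FALSE)
  structure(list(k_max = k_max, km_na = km_na, km_k = km_k,
                 h_na = h_na, h_k = h_k, n_copies = n_copies,
                 stoichiometry = c(na = -3, k = +2)),
            class = "pump_params")
}

#' Electrodiffusive channel parameters
#'
#' A Goldman-Hodgkin-Katz (constant-field) conductive pathway for one ion on
#' one membrane (or the paracellular shunt).
#'
#' @param p_area permeability-area product (m^3/s per cell).
#' @param valence ion valence, -1 or +1.
#' @param membrane `"apical"`, `"basolateral"` or `"paracellular"`.
#' @return Object of class `channel_params`.
#' @export
channel_params <- function(p_area, valence,
                           membrane = c("apical", "basolateral", "paracellular")) {
  membrane <- match.arg(membrane)
  if (!is.finite(p_area) || p_area < 0)
    stop("channel_params: p_area must be >= 0", call. = FALSE)
  if (!valence %in% c(-1, 1))
    stop("channel_params: valence must be -1 or +1", call. = FALSE)
  structure(list(p_area = p_area, valence = valence, membrane = membrane),
            class = "channel_params")
}

#' Osmotic water pathway parameters
#'
#' @param lp osmotic water permeability-area product (m^3/s per mOsm, i.e.
#'   per mol/m^3 of osmotic difference) for one pathway.
#' @param membrane `"apical"`, `"basolateral"` or `"paracellular"`.
#' @param sigma named reflection coefficients per solute in `[0, 1]`
#'   (default 1 for all of na, k, cl, hco3, glucose).
#' @return Object of class `water_params`.
#' @export
water_params <- function(lp,
                         membrane = c("apical", "basolateral", "paracellular"),
                         sigma = c(na = 1, k = 1, cl = 1, hco3 = 1, glucose = 1)) {
  membrane <- match.arg(membrane)
  if (!is.finite(lp) || lp < 0)
    stop("water_params: lp must be >= 0", call. = FALSE)
  need <- c("na", "k", "cl", "hco3", "glucose")
  if (!all(need %in% names(sigma)))
    stop("water_params: sigma must name all of na, k, cl, hco3, glucose",
         call. = FALSE)
  sigma <- sigma[need]
  if (any(sigma < 0 | sigma > 1))
    stop("water_params: reflection coefficients must lie in [0, 1]", call. = FALSE)
  structure(list(lp = lp, membrane = membrane, sigma = sigma),
            class = "water_params")
}
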