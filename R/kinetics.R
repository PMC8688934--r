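# Per-transporter flux laws. Pure kernels: no file I/O, no global state.
# Sign convention: fluxes are positive INTO the cell (or into the compartment
# designated "in" for the generic channel law).

# --- SGLT1 six-state cycle ---------------------------------------------------

# Build the 12 directed transition rates of the cycle for given bath
# conditions. v is the apical membrane potential in volts (cell minus lumen).
sglt1_rates <- function(na_out, glc_out, na_in, glc_in, v, params) {
  k <- params$rates
  q <- params$charges
  u2 <- v / (2 * .RT_F)
  f12 <- exp(-q[["q12"]] * u2); b12 <- 1 / f12
  f34 <- exp(-q[["q34"]] * u2); b34 <- 1 / f34
  f61 <- exp(-q[["q61"]] * u2); b61 <- 1 / f61
  list(
    r12 = k[["k12"]] * na_out^2 * f12, r21 = k[["k21"]] * b12,
    r23 = k[["k23"]] * glc_out,        r32 = k[["k32"]],
    r34 = k[["k34"]] * f34,            r43 = k[["k43"]] * b34,
    r45 = k[["k45"]],                  r54 = k[["k54"]] * glc_in,
    r56 = k[["k56"]],                  r65 = k[["k65"]] * na_in^2,
    r61 = k[["k61"]] * f61,            r16 = k[["k16"]] * b61
  )
}

# Assemble the 6x6 master-equation matrix from the directed rate list.
sglt1_matrix <- function(r) {
  fw <- c(r$r12, r$r23, r$r34, r$r45, r$r56, r$r61)  # i -> i+1 (mod 6)
  bw <- c(r$r21, r$r32, r$r43, r$r54, r$r65, r$r16)  # i+1 -> i
  A <- matrix(0, 6, 6)
  for (i in 1:6) {
    j <- if (i == 6) 1L else i + 1L
    A[i, i] <- A[i, i] - fw[i]; A[j, i] <- A[j, i] + fw[i]
    A[j, j] <- A[j, j] - bw[i]; A[i, j] <- A[i, j] + bw[i]
  }
  A
}

# Net clockwise cycle rate per transporter (1/s). v in volts.
sglt1_cycle_rate <- function(na_out, glc_out, na_in, glc_in, v, params) {
  r <- sglt1_rates(na_out, glc_out, na_in, glc_in, v, params)
  A <- sglt1_matrix(r)
  A[6, ] <- 1
  p <- tryCatch(solve(A, c(0, 0, 0, 0, 0, 1)), error = function(e)
    stop("sglt1: singular occupancy system (degenerate rate constants)",
         call. = FALSE))
  r$r34 * p[3] - r$r43 * p[4]
}

#' Steady-state occupancy of the SGLT1 six-state cycle
#'
#' Solves the master-equation steady state `A p = 0` subject to
#' `sum(p) = 1`, where `A` is the 6 x 6 transition-rate matrix of the cycle.
#'
#' @param na_out,glc_out luminal Na+ and glucose (mM).
#' @param na_in,glc_in intracellular Na+ and glucose (mM).
#' @param v_apical apical membrane potential (mV, cell relative to lumen).
#' @param params an [sglt1_params()] object.
#' @return Named list with `p` (occupancies, length 6, summing to 1) and
#'   `cycle_rate` (net clockwise cycle rate per transporter, 1/s).
#' @export
sglt1_occupancy <- function(na_out, glc_out, na_in, glc_in, v_apical, params) {
  r <- sglt1_rates(na_out, glc_out, na_in, glc_in, mv_to_v(v_apical), params)
  A <- sglt1_matrix(r)
  A[6, ] <- 1                       # occupancy closure replaces one balance row
  p <- tryCatch(solve(A, c(0, 0, 0, 0, 0, 1)), error = function(e)
    stop("sglt1_occupancy: singular occupancy system (degenerate rate constants)",
         call. = FALSE))
  list(p = p, cycle_rate = r$r34 * p[3] - r$r43 * p[4])
}

#' Glucose and sodium flux through SGLT1
#'
#' Steady-state flux of the six-state cotransporter cycle. Each forward cycle
#' moves one glucose and two Na+ from the lumen into the cell. Net reverse
#' (cell-to-lumen) transport is clamped to zero: the clamp applies to the whole
#' coupled cycle, so the 2:1 Na:glucose coupling is preserved exactly.
#'
#' @param lumen,cell [compartment_state()] objects (lumen-side and cell-side).
#' @param v_apical apical membrane potential (mV, cell relative to lumen).
#' @param params an [sglt1_params()] object.
#' @return Named numeric vector: `glucose` and `na` fluxes (mol/s, positive
#'   into the cell), per cell (`n_copies` included).
#' @examples
#' p <- sglt1_params()
#' lum <- compartment_state(150, 5, 150, glucose = 10, role = "lumen")
#' cyt <- compartment_state(50, 95, 45, glucose = 5, role = "cell")
#' sglt1_flux(lum, cyt, v_apical = -65, params = p)
#' @export
sglt1_flux <- function(lumen, cell, v_apical, params) {
  occ <- sglt1_occupancy(lumen$na, lumen$glucose, cell$na, cell$glucose,
                         v_apical, params)
  per_copy <- max(occ$cycle_rate, 0) / .AVOGADRO   # mol/s per transporter
  j_glc <- params$n_copies * per_copy
  c(glucose = j_glc, na = 2 * j_glc)
}

# --- GLUT2 alternating-conformation carrier ---------------------------------

# Net carrier turnover per copy (1/s), positive from side a ("out") to b ("in").
# States: 1 outward empty, 2 outward loaded, 3 inward loaded, 4 inward empty.
glut2_cycle_rate <- function(glc_a, glc_b, params) {
  k <- params$rates
  fw <- c(k[[1]] * glc_a, k[[5]], k[[4]], k[[7]])  # 1->2, 2->3, 3->4, 4->1
  bw <- c(k[[2]], k[[6]], k[[3]] * glc_b, k[[8]])  # 2->1, 3->2, 4->3, 1->4
  A <- matrix(0, 4, 4)
  for (i in 1:4) {
    j <- if (i == 4) 1L else i + 1L
    A[i, i] <- A[i, i] - fw[i]; A[j, i] <- A[j, i] + fw[i]
    A[j, j] <- A[j, j] - bw[i]; A[i, j] <- A[i, j] + bw[i]
  }
  A[4, ] <- 1
  p <- solve(A, c(0, 0, 0, 1))
  k[[5]] * p[2] - k[[6]] * p[3]
}

#' Glucose flux through an alternating-conformation carrier (GLUT2)
#'
#' Facilitated diffusion through a four-state carrier cycle. Flux is positive
#' from `side_a` to `side_b`, vanishes when the two concentrations are equal
#' (passive carrier, detailed balance enforced by construction), and saturates
#' in both substrates.
#'
#' @param side_a,side_b glucose concentrations (mM) on the two faces.
#' @param params a [carrier_params()] object.
#' @return Flux in mol/s from a to b, per cell (`n_copies` included).
#' @examples
#' glut2_flux(10, 10, carrier_params())   # 0: passive carrier at equilibrium
#' glut2_flux(50, 5, carrier_params())
#' @export
glut2_flux <- function(side_a, side_b, params) {
  if (!is.finite(side_a) || !is.finite(side_b) || side_a < 0 || side_b < 0)
    stop("glut2_flux: concentrations must be finite and >= 0", call. = FALSE)
  params$n_copies * glut2_cycle_rate(side_a, side_b, params) / .AVOGADRO
}

# --- Na+/K+-ATPase -----------------------------------------------------------

#' Na+/K+-ATPase pump flux
#'
#' Hill-type forward-only pump law saturating in intracellular Na+ (Hill
#' exponent 3) and extracellular K+ (Hill exponent 2), exporting 3 Na+ and
#' importing 2 K+ per cycle.
#'
#' @param cell cell-side [compartment_state()] (supplies intracellular Na+).
#' @param bath bath-side [compartment_state()] (supplies extracellular K+).
#' @param params a [pump_params()] object.
#' @return Named numeric vector: `na` (mol/s, <= 0, out of the cell) and
#'   `k` (mol/s, >= 0, into the cell), per cell.
#' @export
pump_flux <- function(cell, bath, params) {
  rate <- pump_cycle_rate(cell$na, bath$k, params)
  j <- params$n_copies * rate / .AVOGADRO
  c(na = -3 * j, k = 2 * j)
}

pump_cycle_rate <- function(na_in, k_out, params) {
  fna <- (na_in / (na_in + params$km_na))^params$h_na
  fk  <- (k_out / (k_out + params$km_k))^params$h_k
  params$k_max * fna * fk
}

# --- Goldman-Hodgkin-Katz channel flux --------------------------------------

#' Constant-field (GHK) electrodiffusive ion flux
#'
#' @param c_in,c_out ion concentrations (mM) on the "in" and "out" side of
#'   the pathway.
#' @param v membrane potential in mV, "in" side relative to "out" side.
#' @param params a [channel_params()] object (permeability-area product and
#'   valence).
#' @return Ion flux in mol/s, positive into the "in" compartment. Reduces to
#'   `p_area * (c_out - c_in)` as `v -> 0`; changes sign exactly at the
#'   Nernst potential.
#' @export
ghk_flux <- function(c_in, c_out, v, params) {
  if (any(c(c_in, c_out) < 0) || !all(is.finite(c(c_in, c_out, v))))
    stop("ghk_flux: concentrations must be >= 0 and inputs finite", call. = FALSE)
  u <- params$valence * mv_to_v(v) / .RT_F
  params$p_area * .ghk_shape(c_in, c_out, u)
}

# (c_out - c_in e^u) * u / (e^u - 1), series-expanded near u = 0.
.ghk_shape <- function(c_in, c_out, u) {
  if (abs(u) < 1e-4) {
    # u/(e^u - 1) = 1 - u/2 + u^2/12 + O(u^4)
    g <- 1 - u / 2 + u * u / 12
    (c_out - c_in * exp(u)) * g
  } else {
    u * (c_out - c_in * exp(u)) / (exp(u) - 1)
  }
}

# --- Osmotic water flux ------------------------------------------------------

#' Osmotic water flux through one pathway
#'
#' Linear osmotic law with per-solute reflection coefficients: volume flow
#' from side a to side b is `lp * sum(sigma_s * (c_s,b - c_s,a))`, positive
#' towards the hyperosmolar side.
#'
#' @param state_a,state_b [compartment_state()] objects, or plain osmolarity
#'   values (mOsm) for a pure-osmolarity call.
#' @param params a [water_params()] object.
#' @param config optional [model_config()] so impermeant cell osmolytes are
#'   counted when a cell state is passed.
#' @return Volumetric water flux (m^3/s) from a to b.
#' @export
water_flux <- function(state_a, state_b, params, config = NULL) {
  eff_osm <- function(s) {
    if (is.numeric(s)) return(sum(s))   # already an osmolarity
    o <- sum(params$sigma * c(s$na, s$k, s$cl, s$hco3, s$glucose))
    if (identical(s$role, "cell") && !is.null(config))
      o <- o + config$osmolytes$amount / s$volume   # sigma 1 for impermeants
    o
  }
  params$lp * (eff_osm(state_b) - eff_osm(state_a))
}
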