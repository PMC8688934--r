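# Assembly of the three-compartment cell model: per-membrane flux sets,
# quasi-steady membrane potentials from current balance, and the governing
# balance equations for cell amounts/volume and blood composition.
#
# Potential convention: phi_blood = 0.  v_apical = phi_cell - phi_lumen and
# v_basolateral = phi_cell - phi_blood (both in mV, negative at baseline).
# The paracellular shunt sees phi_blood - phi_lumen = v_apical - v_basolateral.
#
# Internally states move as plain 5-vectors (na, k, cl, hco3, glucose in mM)
# plus volumes; the compartment_state class is the user-facing container.

.SPECIES <- c("na", "k", "cl", "hco3", "glucose")
.zvec <- c(na = 1, k = 1, cl = -1, hco3 = -1, glucose = 0)

#' Construct the state triplet at default initial conditions
#'
#' Baths are initialised at 150 mM Na+, 5 mM K+, 150 mM Cl- (blood glucose at
#' the inflow value); the cell starts at a generic physiological composition
#' and is usually relaxed to its zero-glucose steady state before use.
#'
#' @param config a [model_config()].
#' @return Named list of three [compartment_state()] objects
#'   (`lumen`, `cell`, `blood`).
#' @export
initial_states <- function(config) {
  lum <- config$lumen
  bld <- config$blood_inflow
  list(
    lumen = compartment_state(lum$na, lum$k, lum$cl, lum$hco3, lum$glucose,
                              ph = lum$ph,
                              volume = if (config$lumen_finite)
                                config$lumen_volume else 1e-12,
                              role = "lumen"),
    cell  = compartment_state(na = 50, k = 95, cl = 45, hco3 = 25, glucose = 1,
                              ph = 7.1, volume = 1e-15, role = "cell"),
    blood = compartment_state(bld$na, bld$k, bld$cl, bld$hco3, bld$glucose,
                              ph = bld$ph, volume = config$blood_volume,
                              role = "blood")
  )
}

state_vec <- function(s) c(s$na, s$k, s$cl, s$hco3, s$glucose)

# --- Compiled representation of the channel set ------------------------------

# Precomputes vectors for the GHK channel evaluation and 5 x n incidence
# matrices that accumulate channel fluxes into per-membrane species totals.
compile_model <- function(config) {
  ch <- config$channels
  n <- length(ch)
  memb <- vapply(ch, function(p) match(p$membrane,
                 c("apical", "basolateral", "paracellular")), integer(1))
  ion <- match(sub("^(ap|bl|pc)_", "", names(ch)), .SPECIES)
  if (any(is.na(ion)))
    stop("compile_model: channel names must be <ap|bl|pc>_<ion>", call. = FALSE)
  p <- vapply(ch, function(x) x$p_area, numeric(1))
  z <- vapply(ch, function(x) x$valence, numeric(1))
  inc <- function(m) {
    M <- matrix(0, 5, n)
    for (j in seq_len(n)) if (memb[j] == m) M[ion[j], j] <- 1
    M
  }
  list(n = n, memb = memb, ion = ion, p = p, z = z,
       M_ap = inc(1), M_bl = inc(2), M_pc = inc(3),
       sig_ap = config$water$apical$sigma,
       sig_bl = config$water$basolateral$sigma,
       sig_pc = config$water$paracellular$sigma,
       lp = c(config$water$apical$lp, config$water$basolateral$lp,
              config$water$paracellular$lp),
       inflow = c(config$blood_inflow$na, config$blood_inflow$k,
                  config$blood_inflow$cl, config$blood_inflow$hco3,
                  config$blood_inflow$glucose),
       inflow_h = 10^(-config$blood_inflow$ph) * 1e3)
}

# --- Fast kernels on plain vectors -------------------------------------------

# Vectorized GHK shape: (c_out - c_in e^u) * u/(e^u - 1), series near u = 0.
.ghk_shape_vec <- function(c_in, c_out, u) {
  small <- abs(u) < 1e-4
  out <- numeric(length(u))
  if (any(small)) {
    us <- u[small]
    out[small] <- (c_out[small] - c_in[small] * exp(us)) *
      (1 - us / 2 + us * us / 12)
  }
  if (any(!small)) {
    ub <- u[!small]
    out[!small] <- ub * (c_out[!small] - c_in[!small] * exp(ub)) /
      (exp(ub) - 1)
  }
  out
}

# All channel fluxes (mol/s into the cell; paracellular into the blood).
.channel_fluxes <- function(lum, cell, blood, va, vb, cc) {
  v_m <- c(va, vb, va - vb)[cc$memb] * 1e-3 / .RT_F
  u <- cc$z * v_m
  c_in <- ifelse(cc$memb == 3L, blood[cc$ion], cell[cc$ion])
  c_out <- ifelse(cc$memb == 1L, lum[cc$ion],
                  ifelse(cc$memb == 2L, blood[cc$ion], lum[cc$ion]))
  cc$p * .ghk_shape_vec(c_in, c_out, u)
}

# Voltage-dependent fluxes: SGLT1 pair + channel vector.
.fluxes_electro <- function(lum, cell, blood, va, vb, config, cc) {
  cyc <- sglt1_cycle_rate(lum[1], lum[5], cell[1], cell[5],
                          mv_to_v(va), config$sglt1)
  jglc <- config$sglt1$n_copies * max(cyc, 0) / .AVOGADRO
  list(sglt1_glc = jglc, sglt1_na = 2 * jglc,
       chan = .channel_fluxes(lum, cell, blood, va, vb, cc))
}

# Voltage-independent fluxes: carriers, pump, water.
.fluxes_passive <- function(lum, cell, cell_vol, blood, config, cc) {
  ja <- if (config$glut2_apical$n_copies > 0)
    config$glut2_apical$n_copies *
      glut2_cycle_rate(lum[5], cell[5], config$glut2_apical) / .AVOGADRO else 0
  jb <- if (config$glut2_basolateral$n_copies > 0)
    config$glut2_basolateral$n_copies *
      glut2_cycle_rate(blood[5], cell[5], config$glut2_basolateral) / .AVOGADRO else 0
  pr <- config$pump$n_copies *
    pump_cycle_rate(cell[1], blood[2], config$pump) / .AVOGADRO
  osm_cell <- sum(cell) + config$osmolytes$amount / cell_vol
  osm_cell_ap <- sum(cc$sig_ap * cell) + config$osmolytes$amount / cell_vol
  osm_cell_bl <- sum(cc$sig_bl * cell) + config$osmolytes$amount / cell_vol
  list(glut2_apical = ja, glut2_basolateral = jb,
       pump_na = -3 * pr, pump_k = 2 * pr,
       water_apical = cc$lp[1] * (osm_cell_ap - sum(cc$sig_ap * lum)),
       water_basolateral = cc$lp[2] * (osm_cell_bl - sum(cc$sig_bl * blood)),
       water_paracellular = cc$lp[3] * sum(cc$sig_pc * (blood - lum)),
       osm_cell = osm_cell)
}

# Per-membrane species totals (5-vectors, mol/s into the cell; paracellular
# into the blood).
.species_tables <- function(fe, fp, cc) {
  ap <- as.numeric(cc$M_ap %*% fe$chan)
  bl <- as.numeric(cc$M_bl %*% fe$chan)
  pc <- as.numeric(cc$M_pc %*% fe$chan)
  ap[1] <- ap[1] + fe$sglt1_na
  ap[5] <- ap[5] + fe$sglt1_glc + fp$glut2_apical
  bl[1] <- bl[1] + fp$pump_na
  bl[2] <- bl[2] + fp$pump_k
  bl[5] <- bl[5] + fp$glut2_basolateral
  list(ap = ap, bl = bl, pc = pc)
}

.zv <- c(1, 1, -1, -1, 0)

# Current-balance residuals (amperes per cell) and the largest individual
# current magnitude for relative convergence tests.
.current_residuals <- function(lum, cell, blood, va, vb, config, cc, fp) {
  fe <- .fluxes_electro(lum, cell, blood, va, vb, config, cc)
  tb <- .species_tables(fe, fp, cc)
  i_ap <- .FARADAY * sum(.zv * tb$ap)
  i_bl <- .FARADAY * sum(.zv * tb$bl)
  i_pc <- .FARADAY * sum(.zv * tb$pc)
  scale <- .FARADAY * max(abs(.zv * tb$ap), abs(.zv * tb$bl), abs(.zv * tb$pc))
  list(r = c(i_ap + i_bl, -i_bl + i_pc), scale = scale)
}

# 2-d damped Newton for the potentials. Returns c(va, vb) in mV.
.solve_potentials <- function(lum, cell, blood, config, cc, fp,
                              guess = c(-40, -50), tol = 1e-12) {
  v <- guess
  cr <- .current_residuals(lum, cell, blood, v[1], v[2], config, cc, fp)
  res <- cr$r
  iscale <- max(cr$scale, .FARADAY * 1e-22)
  h <- 1e-4
  it <- 0L
  for (it in seq_len(80)) {
    if (max(abs(res)) <= tol * iscale) break
    r1 <- .current_residuals(lum, cell, blood, v[1] + h, v[2], config, cc, fp)$r
    r2 <- .current_residuals(lum, cell, blood, v[1], v[2] + h, config, cc, fp)$r
    J <- cbind((r1 - res) / h, (r2 - res) / h)
    step <- tryCatch(as.numeric(solve(J, -res)), error = function(e)
      stop("membrane potentials: singular current-balance Jacobian", call. = FALSE))
    smax <- max(abs(step))
    if (smax > 25) step <- step * (25 / smax)
    lambda <- 1
    repeat {
      vn <- v + lambda * step
      crn <- .current_residuals(lum, cell, blood, vn[1], vn[2], config, cc, fp)
      if (sum(crn$r^2) < sum(res^2) || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    v <- vn; res <- crn$r
    iscale <- max(crn$scale, .FARADAY * 1e-22)
  }
  if (max(abs(res)) > 1e-6 * iscale)
    stop(sprintf(
      "membrane potentials: current balance did not converge (residual %.3g A at va=%.2f, vb=%.2f mV)",
      max(abs(res)), v[1], v[2]), call. = FALSE)
  structure(v, residual = res, iterations = it)
}

# --- Public interfaces -------------------------------------------------------

#' Quasi-steady membrane potentials from charge conservation
#'
#' Solves the two-equation current-balance system (zero net current into the
#' cell; zero net current into the blood, the paracellular shunt closing the
#' transepithelial circuit) for the apical and basolateral membrane
#' potentials by damped Newton iteration with a finite-difference Jacobian.
#'
#' @param lumen,cell,blood [compartment_state()] objects.
#' @param config a [model_config()].
#' @param guess starting values `c(va, vb)` in mV.
#' @param tol convergence tolerance on the residual relative to the largest
#'   individual membrane current.
#' @return Named list: `v_apical`, `v_basolateral` (mV), `residual` (A),
#'   `iterations`.
#' @export
membrane_potentials <- function(lumen, cell, blood, config,
                                guess = c(-40, -50), tol = 1e-12) {
  cc <- compile_model(config)
  lu <- state_vec(lumen); ce <- state_vec(cell); bl <- state_vec(blood)
  fp <- .fluxes_passive(lu, ce, cell$volume, bl, config, cc)
  v <- .solve_potentials(lu, ce, bl, config, cc, fp, guess = guess, tol = tol)
  list(v_apical = v[1], v_basolateral = v[2],
       residual = attr(v, "residual"), iterations = attr(v, "iterations"))
}

#' Compute all pathway fluxes at given membrane potentials
#'
#' @param lumen,cell,blood [compartment_state()] objects.
#' @param va,vb apical and basolateral membrane potentials (mV).
#' @param config a [model_config()].
#' @return A `flux_report`: named list of per-pathway fluxes (mol/s, positive
#'   into the cell; paracellular entries positive into the blood; water fluxes
#'   in m^3/s).
#' @export
compute_fluxes <- function(lumen, cell, blood, va, vb, config) {
  cc <- compile_model(config)
  lu <- state_vec(lumen); ce <- state_vec(cell); bl <- state_vec(blood)
  fp <- .fluxes_passive(lu, ce, cell$volume, bl, config, cc)
  fe <- .fluxes_electro(lu, ce, bl, va, vb, config, cc)
  flux_report(fe, fp, cc, va, vb)
}

flux_report <- function(fe, fp, cc, va, vb) {
  chan <- stats::setNames(fe$chan, names(cc$memb))
  structure(list(
    sglt1 = c(glucose = fe$sglt1_glc, na = fe$sglt1_na),
    glut2_apical = fp$glut2_apical,
    glut2_basolateral = fp$glut2_basolateral,
    pump = c(na = fp$pump_na, k = fp$pump_k),
    channels = as.list(chan),
    water_apical = fp$water_apical,
    water_basolateral = fp$water_basolateral,
    water_paracellular = fp$water_paracellular,
    v_apical = va, v_basolateral = vb), class = "flux_report")
}

# --- State vector packing ----------------------------------------------------

state_names <- function(config) {
  nm <- c(paste0("cell_", c(.SPECIES, "h")), "cell_vol",
          paste0("blood_", c(.SPECIES, "h")))
  if (config$lumen_finite)
    nm <- c(nm, paste0("lumen_", .SPECIES), "lumen_vol")
  nm
}

# Cell entries are amounts (mol) and volume (m^3); blood entries are
# concentrations (mM); finite-lumen entries are amounts and volume.
pack_states <- function(states, config) {
  cl <- states$cell; bl <- states$blood
  h_cell <- 10^(-cl$ph) * 1e3 * cl$volume       # mol
  y <- c(state_vec(cl) * cl$volume, h_cell, cl$volume,
         state_vec(bl), 10^(-bl$ph) * 1e3)
  if (config$lumen_finite) {
    lu <- states$lumen
    y <- c(y, state_vec(lu) * lu$volume, lu$volume)
  }
  stats::setNames(y, state_names(config))
}

# Forgive round-off-scale negative concentrations (clamped to zero); genuine
# domain violations still error, which the integrator treats as a rejected step.
.clamp_tiny <- function(x) ifelse(x < 0 & x > -1e-9, 0, x)

unpack_states <- function(y, config) {
  vc <- y[[7]]
  cc <- .clamp_tiny(c(y[[1]], y[[2]], y[[3]], y[[4]], y[[5]]) / vc)
  cell <- compartment_state(cc[1], cc[2], cc[3], cc[4], cc[5],
                            ph = -log10(max(y[[6]] / vc, 1e-30) / 1e3),
                            volume = vc, role = "cell")
  bc <- .clamp_tiny(c(y[[8]], y[[9]], y[[10]], y[[11]], y[[12]]))
  blood <- compartment_state(bc[1], bc[2], bc[3], bc[4], bc[5],
                             ph = -log10(max(y[[13]], 1e-30) / 1e3),
                             volume = config$blood_volume, role = "blood")
  if (config$lumen_finite) {
    vl <- y[[19]]
    lc <- .clamp_tiny(c(y[[14]], y[[15]], y[[16]], y[[17]], y[[18]]) / vl)
    lumen <- compartment_state(lc[1], lc[2], lc[3], lc[4], lc[5],
                               ph = config$lumen$ph, volume = vl, role = "lumen")
  } else {
    lu <- config$lumen
    lumen <- compartment_state(lu$na, lu$k, lu$cl, lu$hco3, lu$glucose,
                               ph = lu$ph, volume = 1e-12, role = "lumen")
  }
  list(lumen = lumen, cell = cell, blood = blood)
}

# --- Governing equations -----------------------------------------------------

# Fast core: y is the packed state; cc the compiled config. Returns
# derivatives, potentials and the raw flux pieces.
.rhs_core <- function(y, config, cc, v_guess = c(-40, -50)) {
  vc <- y[[7]]
  if (!is.finite(vc) || vc <= 0) stop("negative cell volume", call. = FALSE)
  ce <- .clamp_tiny(c(y[[1]], y[[2]], y[[3]], y[[4]], y[[5]]) / vc)
  bl <- .clamp_tiny(c(y[[8]], y[[9]], y[[10]], y[[11]], y[[12]]))
  if (any(ce < 0) || any(bl < 0)) stop("negative concentration", call. = FALSE)
  if (config$lumen_finite) {
    vl <- y[[19]]
    if (!is.finite(vl) || vl <= 0) stop("negative lumen volume", call. = FALSE)
    lu <- .clamp_tiny(c(y[[14]], y[[15]], y[[16]], y[[17]], y[[18]]) / vl)
    if (any(lu < 0)) stop("negative concentration", call. = FALSE)
  } else {
    lu <- c(config$lumen$na, config$lumen$k, config$lumen$cl,
            config$lumen$hco3, config$lumen$glucose)
  }
  fp <- .fluxes_passive(lu, ce, vc, bl, config, cc)
  v <- .solve_potentials(lu, ce, bl, config, cc, fp, guess = v_guess)
  fe <- .fluxes_electro(lu, ce, bl, v[1], v[2], config, cc)
  tb <- .species_tables(fe, fp, cc)

  dcell <- tb$ap + tb$bl                         # mol/s into the cell
  dvol  <- fp$water_apical + fp$water_basolateral

  q_in <- config$blood_flow
  water_into_blood <- -fp$water_basolateral + fp$water_paracellular
  q_out <- q_in + water_into_blood
  if (q_out < 0)
    stop("outlet blood flow is negative; configuration error", call. = FALSE)
  dblood <- (q_in * cc$inflow - q_out * bl - tb$bl + tb$pc) / config$blood_volume
  dblood_h <- (q_in * cc$inflow_h - q_out * y[[13]]) / config$blood_volume

  dy <- c(dcell, 0, dvol, dblood, dblood_h)      # cell H+ inert by default
  if (config$lumen_finite) {
    dlum <- -tb$ap - tb$pc
    dlum_vol <- -fp$water_apical - fp$water_paracellular
    dy <- c(dy, dlum, dlum_vol)
  }
  list(dy = dy, v = as.numeric(v), fe = fe, fp = fp, tb = tb, q_out = q_out)
}

#' Time derivatives of the cell and blood balances
#'
#' Returns d(amount)/dt for every cell species, dV_cell/dt from the osmotic
#' water balance, and d(concentration)/dt for the blood compartment, whose
#' volume is held fixed by setting the outlet flow to inlet flow plus the
#' water gained across the basolateral membrane and the paracellular path.
#' Membrane potentials are treated as fast algebraic variables: the
#' current-balance system is solved inside the right-hand side.
#'
#' @param y packed state vector (see [initial_states()]; cell species as
#'   amounts in mol plus volume in m^3, blood species as concentrations in mM).
#' @param config a [model_config()].
#' @param v_guess warm-start guess for the membrane potentials (mV).
#' @return List with `dy` (derivatives), `v` (potentials, mV) and `fluxes`
#'   (a `flux_report`).
#' @export
model_rhs <- function(y, config, v_guess = c(-40, -50)) {
  cc <- compile_model(config)
  core <- .rhs_core(y, config, cc, v_guess)
  list(dy = stats::setNames(core$dy, state_names(config)),
       v = core$v,
       fluxes = flux_report(core$fe, core$fp, cc, core$v[1], core$v[2]),
       q_out = core$q_out)
}

#' @export
print.flux_report <- function(x, ...) {
  cat("<flux_report> (mol/s into the cell; water m^3/s)\n")
  cat(sprintf("  SGLT1: glucose %.3e, Na %.3e\n",
              x$sglt1[["glucose"]], x$sglt1[["na"]]))
  cat(sprintf("  GLUT2 apical %.3e | basolateral %.3e\n",
              x$glut2_apical, x$glut2_basolateral))
  cat(sprintf("  pump: Na %.3e, K %.3e\n", x$pump[["na"]], x$pump[["k"]]))
  cat(sprintf("  water: apical %.3e, basolateral %.3e, paracellular %.3e\n",
              x$water_apical, x$water_basolateral, x$water_paracellular))
  cat(sprintf("  potentials: va %.2f mV, vb %.2f mV\n",
              x$v_apical, x$v_basolateral))
  invisible(x)
}
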