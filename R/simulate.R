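# Protocol-driven time integration and steady-state location.

#' Stimulus protocol
#'
#' A piecewise-constant schedule of luminal composition and configuration
#' overrides. Each event names a time (s) and the changes applied from that
#' time on; integration is restarted exactly at every event time, never
#' interpolated through a discontinuity.
#'
#' @param t_end total simulated time (s).
#' @param events list of events, each a list with `time` (s), optionally
#'   `lumen` (named list of luminal composition overrides, mM) and optionally
#'   `config` (function taking and returning a [model_config()]).
#' @param record_dt output grid spacing (s).
#' @return Object of class `protocol`.
#' @examples
#' # Glucose step: 0 mM for 5000 s, then 50 mM up to 10000 s
#' p <- protocol(10000, events = list(
#'   list(time = 0, lumen = list(glucose = 0)),
#'   list(time = 5000, lumen = list(glucose = 50))))
#' @export
protocol <- function(t_end, events = list(list(time = 0)), record_dt = 20) {
  times <- vapply(events, function(e) as.numeric(e$time), numeric(1))
  if (any(diff(times) <= 0)) stop("protocol: event times must be strictly increasing",
                                  call. = FALSE)
  if (times[1] != 0) stop("protocol: first event must be at time 0", call. = FALSE)
  if (t_end < times[length(times)])
    stop("protocol: t_end earlier than the last event", call. = FALSE)
  structure(list(t_end = t_end, events = events, record_dt = record_dt),
            class = "protocol")
}

apply_event <- function(config, event) {
  if (!is.null(event$lumen))
    for (nm in names(event$lumen)) config$lumen[[nm]] <- event$lumen[[nm]]
  if (!is.null(event$config)) config <- event$config(config)
  config
}

# RHS closure with warm-started membrane potentials; returns NULL outside the
# physical domain (step-rejection signal for the integrator). The channel set
# is compiled once per configuration.
make_rhs <- function(config) {
  cc <- compile_model(config)
  cache <- new.env(parent = emptyenv())
  cache$v <- c(-40, -50)
  function(y) {
    out <- tryCatch(.rhs_core(y, config, cc, v_guess = cache$v),
                    error = function(e) NULL)
    if (is.null(out)) return(NULL)
    cache$v <- out$v
    out$dy
  }
}

#' Integrate the model under a stimulus protocol
#'
#' Stiff implicit integration of the cell/blood balance equations with the
#' luminal bath and configuration switched exactly at the protocol's event
#' times (solver restart, not interpolation).
#'
#' @param prot a [protocol()].
#' @param config a [model_config()].
#' @param initial optional state triplet (as from [initial_states()] or a
#'   previous steady state); defaults to [initial_states()].
#' @param rtol relative solver tolerance.
#' @return Object of class `trajectory`: a data frame of time (s), compartment
#'   states (concentrations mM, cell volume m^3, potentials mV) and
#'   per-pathway fluxes, plus solver diagnostics in attributes.
#' @export
integrate_protocol <- function(prot, config, initial = NULL, rtol = 1e-5) {
  stopifnot(inherits(prot, "protocol"))
  if (is.null(initial)) initial <- initial_states(config)
  times <- vapply(prot$events, function(e) e$time, numeric(1))
  bounds <- c(times, prot$t_end)
  grid_all <- numeric(0)
  rows <- list()
  cfg <- config
  y <- NULL
  diag_steps <- 0L
  for (i in seq_along(prot$events)) {
    cfg <- apply_event(cfg, prot$events[[i]])
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    if (is.null(y)) {
      st <- initial
      st$lumen <- initial_states(cfg)$lumen   # lumen always follows config
      y <- pack_states(st, cfg)
    }
    if (t1 > t0) {
      f <- make_rhs(cfg)
      sol <- ros2_integrate(f, y, t0, t1, rtol = rtol)
      diag_steps <- diag_steps + sol$steps
      grid <- unique(c(seq(t0, t1, by = prot$record_dt), t1))
      yg <- vapply(seq_along(y), function(j)
        stats::approx(sol$t, sol$y[, j], xout = grid, rule = 2)$y,
        numeric(length(grid)))
      for (r in seq_along(grid)) {
        yr <- stats::setNames(yg[r, ], names(y))
        rows[[length(rows) + 1L]] <- trajectory_row(grid[r], yr, cfg)
      }
      grid_all <- c(grid_all, grid)
      y <- stats::setNames(sol$y[nrow(sol$y), ], names(y))
    } else {
      rows[[length(rows) + 1L]] <- trajectory_row(t0, y, cfg)
      grid_all <- c(grid_all, t0)
    }
  }
  if (length(rows) == 0) { # zero-length protocol: initial state only
    rows[[1]] <- trajectory_row(0, y, cfg)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df, class = c("trajectory", "data.frame"),
            config = cfg, steps = diag_steps, final_y = y)
}

# One output row: states + potentials + fluxes.
trajectory_row <- function(t, y, config) {
  out <- model_rhs(y, config)
  st <- unpack_states(y, config)
  fl <- out$fluxes
  data.frame(
    time_s = t,
    lumen_glucose_mM = st$lumen$glucose,
    cell_na_mM = st$cell$na, cell_k_mM = st$cell$k, cell_cl_mM = st$cell$cl,
    cell_hco3_mM = st$cell$hco3, cell_glucose_mM = st$cell$glucose,
    cell_ph = st$cell$ph, cell_volume_m3 = st$cell$volume,
    blood_na_mM = st$blood$na, blood_k_mM = st$blood$k,
    blood_cl_mM = st$blood$cl, blood_glucose_mM = st$blood$glucose,
    v_apical_mV = fl$v_apical, v_basolateral_mV = fl$v_basolateral,
    sglt1_glucose_mol_s = fl$sglt1[["glucose"]],
    sglt1_na_mol_s = fl$sglt1[["na"]],
    glut2_apical_mol_s = fl$glut2_apical,
    glut2_basolateral_mol_s = fl$glut2_basolateral,
    pump_na_mol_s = fl$pump[["na"]], pump_k_mol_s = fl$pump[["k"]],
    water_apical_m3_s = fl$water_apical,
    water_basolateral_m3_s = fl$water_basolateral,
    water_paracellular_m3_s = fl$water_paracellular
  )
}

#' Locate a steady state of the model
#'
#' Pseudo-transient continuation (stiff integration over growing horizons)
#' until the maximum relative rate of change drops below `rate_tol` per
#' second, followed by a damped Newton polish of the right-hand side.
#'
#' @param config a [model_config()].
#' @param initial optional state triplet; defaults to [initial_states()].
#' @param rate_tol steady-state threshold: max over states of
#'   `|dy/dt| * 1 s / max(|y|, scale)` (default 1e-9).
#' @param t_relax initial relaxation horizon (s); grown by doubling up to
#'   `10 * t_max` before declaring failure.
#' @param t_max nominal horizon (s), default 10000.
#' @return Object of class `steady_state_result`: `states` (triplet),
#'   `fluxes`, `v_apical`, `v_basolateral` (mV), `residual` (1/s),
#'   `converged`, `horizon_used` (s).
#' @export
find_steady_state <- function(config, initial = NULL, rate_tol = 1e-9,
                              t_relax = 2000, t_max = 10000) {
  if (is.null(initial)) initial <- initial_states(config)
  st <- initial
  st$lumen <- initial_states(config)$lumen
  y <- pack_states(st, config)
  f <- make_rhs(config)
  scales <- solver_scales(y)
  relrate <- function(yv) {
    dv <- f(yv)
    if (is.null(dv)) return(Inf)
    max(abs(dv) / pmax(abs(yv), scales))
  }
  # The flow conserves cell charge exactly (the potential solve zeroes the net
  # membrane current), and HCO3-/H+ are inert unless given a pathway, so the
  # raw RHS Jacobian is singular. For the Newton polish those redundant rows
  # are replaced by the corresponding conservation/pinning constraints, all
  # expressed in mol/s against a 1 s horizon.
  zq <- c(1, 1, -1, -1, 0)
  charge_of <- function(yv) sum(zq * yv[1:5]) +
    config$osmolytes$valence * config$osmolytes$amount
  q0 <- charge_of(y)
  hco3_live <- any(vapply(config$channels, function(ch) ch$valence == -1 &&
                            ch$membrane != "paracellular", logical(1)) &
                   grepl("hco3", names(config$channels)))
  h0 <- y[["cell_h"]]; nhco3_0 <- y[["cell_hco3"]]
  f_newton <- function(yv) {
    r <- f(yv)
    if (is.null(r)) return(NULL)
    r[3] <- charge_of(yv) - q0                  # replaces the Cl- balance row
    r[6] <- yv[[6]] - h0                        # inert cell H+
    if (!hco3_live) r[4] <- yv[[4]] - nhco3_0   # inert cell HCO3-
    r
  }
  horizon <- 0
  span <- t_relax
  repeat {
    # Newton polish attempt (cheap; succeeds once in the basin of attraction)
    ns <- newton_steady(f_newton, y, scales = scales, tol = rate_tol)
    if (ns$converged && all(is.finite(ns$y)) && relrate(ns$y) < rate_tol) {
      y <- ns$y
      break
    }
    if (horizon >= 10 * t_max) {
      return(steady_state_result(y, config, residual = relrate(y),
                                 converged = relrate(y) < rate_tol,
                                 horizon = horizon))
    }
    sol <- ros2_integrate(f, y, 0, span, rtol = 1e-5)
    y <- stats::setNames(sol$y[nrow(sol$y), ], names(y))
    horizon <- horizon + span
    span <- span * 2
  }
  steady_state_result(y, config, residual = relrate(y), converged = TRUE,
                      horizon = horizon)
}

steady_state_result <- function(y, config, residual, converged, horizon) {
  out <- model_rhs(y, config)
  structure(list(states = unpack_states(y, config),
                 fluxes = out$fluxes,
                 v_apical = out$fluxes$v_apical,
                 v_basolateral = out$fluxes$v_basolateral,
                 residual = residual,
                 converged = converged,
                 horizon_used = horizon,
                 y = y),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("<steady_state_result> converged: %s (residual %.2e /s)\n",
              x$converged, x$residual))
  cl <- x$states$cell; bl <- x$states$blood
  cat(sprintf("  cell: Na %.1f K %.1f Cl %.1f glc %.2f mM, pH %.2f, V %.3e m^3\n",
              cl$na, cl$k, cl$cl, cl$glucose, cl$ph, cl$volume))
  cat(sprintf("  blood: Na %.1f K %.1f Cl %.1f glc %.2f mM\n",
              bl$na, bl$k, bl$cl, bl$glucose))
  cat(sprintf("  potentials: va %.1f mV, vb %.1f mV\n",
              x$v_apical, x$v_basolateral))
  invisible(x)
}
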