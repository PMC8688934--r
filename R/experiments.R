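# Scenario runners: transporter flux curves and their equivalent
# Michaelis-Menten summaries, the glucose-step protocol, and the steady-state
# parameter sweeps (luminal glucose, transporter density, blood flow, GLUT2
# translocation, SGLT1 upregulation, perfused-loop comparison).

#' Transporter flux-versus-luminal-glucose curves
#'
#' Computes the isolated-transporter flux curves: SGLT1 at fixed apical
#' potential and luminal Na+, and apical GLUT2, each against luminal glucose
#' at a fixed intracellular glucose, scaled to umol/(min cm) of intestine.
#'
#' @param glucose_lumen luminal glucose grid (mM).
#' @param gi intracellular glucose (mM).
#' @param v_apical apical membrane potential (mV); the published curves use
#'   -65 mV.
#' @param na_lumen luminal Na+ (mM); the published curves use 150 mM.
#' @param na_cell intracellular Na+ (mM); a representative 50 mM is used
#'   (the curve is insensitive to it).
#' @param params transporter parameters ([sglt1_params()] or
#'   [carrier_params()]).
#' @param anatomy an [anatomy_params()] for the per-cm conversion.
#' @return data.frame with `substrate_mM` and `flux_umol_min_cm`.
#' @export
sglt1_flux_curve <- function(glucose_lumen, gi, v_apical = -65,
                             na_lumen = 150, na_cell = 50,
                             params = sglt1_params(n_copies = 3e7),
                             anatomy = anatomy_params()) {
  v <- mv_to_v(v_apical)
  per_copy <- vapply(glucose_lumen, function(g)
    max(sglt1_cycle_rate(na_lumen, g, na_cell, gi, v, params), 0) / .AVOGADRO,
    numeric(1))
  data.frame(substrate_mM = glucose_lumen,
             flux_umol_min_cm = per_cm_scaling(per_copy, params$n_copies,
                                               anatomy))
}

#' @rdname sglt1_flux_curve
#' @export
glut2_flux_curve <- function(glucose_lumen, gi,
                             params = carrier_params(n_copies = 1e8),
                             anatomy = anatomy_params()) {
  per_copy <- vapply(glucose_lumen, function(g)
    glut2_cycle_rate(g, gi, params) / .AVOGADRO, numeric(1))
  data.frame(substrate_mM = glucose_lumen,
             flux_umol_min_cm = per_cm_scaling(per_copy, params$n_copies,
                                               anatomy))
}

#' Equivalent Vmax/Km table for SGLT1 and apical GLUT2
#'
#' Regenerates the transporter flux curves over a luminal-glucose grid at a
#' set of intracellular glucose levels and fits the equivalent
#' Michaelis-Menten parameters to each curve.
#'
#' For SGLT1 (reverse transport clamped, so the curve starts at zero flux)
#' the fit is the plain `V*S/(Km+S)` against luminal glucose. For the
#' passive GLUT2 carrier the net flux of any alternating-conformation cycle
#' is exactly of Michaelis-Menten form in the excess substrate
#' `x = S - Gi` (it crosses zero at `S = Gi`), so the equivalent parameters
#' are obtained by fitting `V*x/(Km+x)` over the non-negative-excess part of
#' the same curve; a raw fit against `S` has no finite optimum once the
#' negative branch dominates (high `Gi`).
#'
#' @param gi_levels intracellular glucose levels (mM); published table uses
#'   2, 5, 10, 20, 30.
#' @param grid luminal-glucose fit grid (mM); >= 20 points over 0-100 mM.
#' @param config a [model_config()] supplying transporter parameters and copy
#'   numbers (SGLT1 3e7, apical GLUT2 1e8 at baseline).
#' @param anatomy an [anatomy_params()].
#' @return data.frame with one row per `gi` level: equivalent Vmax
#'   (umol/(min cm)) and Km (mM) for both transporters.
#' @export
run_table1 <- function(gi_levels = c(2, 5, 10, 20, 30),
                       grid = seq(0, 100, by = 5),
                       config = model_config(),
                       anatomy = anatomy_params()) {
  rows <- lapply(gi_levels, function(gi) {
    cs <- sglt1_flux_curve(grid, gi, params = config$sglt1, anatomy = anatomy)
    cg <- glut2_flux_curve(grid, gi, params = config$glut2_apical,
                           anatomy = anatomy)
    fs <- fit_michaelis_menten(cs$substrate_mM, cs$flux_umol_min_cm)
    sel <- cg$substrate_mM >= gi
    fg <- fit_michaelis_menten(cg$substrate_mM[sel] - gi,
                               cg$flux_umol_min_cm[sel])
    data.frame(gi_mM = gi,
               sglt1_vmax_umol_min_cm = fs$v_max, sglt1_km_mM = fs$k_m,
               glut2_vmax_umol_min_cm = fg$v_max, glut2_km_mM = fg$k_m)
  })
  do.call(rbind, rows)
}

# --- Whole-cell scenario runners ---------------------------------------------

# Summarise one steady state as a sweep row.
ss_row <- function(ss) {
  st <- ss$states
  data.frame(
    cell_volume_m3 = st$cell$volume,
    cell_glucose_mM = st$cell$glucose,
    cell_na_mM = st$cell$na, cell_k_mM = st$cell$k, cell_cl_mM = st$cell$cl,
    blood_glucose_mM = st$blood$glucose,
    v_apical_mV = ss$v_apical, v_basolateral_mV = ss$v_basolateral,
    sglt1_glucose_mol_s = ss$fluxes$sglt1[["glucose"]],
    glut2_apical_mol_s = ss$fluxes$glut2_apical,
    glut2_basolateral_mol_s = ss$fluxes$glut2_basolateral,
    water_apical_m3_s = ss$fluxes$water_apical,
    water_basolateral_m3_s = ss$fluxes$water_basolateral,
    converged = ss$converged)
}

# Zero-luminal-glucose steady state used as the canonical starting point.
baseline_state <- function(config) {
  find_steady_state(set_luminal_glucose(config, 0))
}

#' Glucose step-stimulus protocol (with and without apical GLUT2)
#'
#' Runs the two-phase protocol: luminal glucose 0 for `t_step` seconds, then
#' `glucose_step` mM up to `t_end`, for the configuration as given and with
#' the apical GLUT2 pool removed. Each run starts from its own zero-glucose
#' steady state; inflowing blood glucose is fixed by the configuration
#' (4 mM at baseline).
#'
#' @param config a [model_config()].
#' @param glucose_step stimulus amplitude (mM), default 50.
#' @param t_step,t_end phase boundary and total time (s), defaults 5000 and
#'   10000.
#' @param record_dt output grid (s).
#' @return List with `with_apical_glut2` and `without_apical_glut2`
#'   trajectories.
#' @export
run_step_stimulus <- function(config, glucose_step = 50, t_step = 5000,
                              t_end = 10000, record_dt = 20) {
  prot <- protocol(t_end, events = list(
    list(time = 0, lumen = list(glucose = 0)),
    list(time = t_step, lumen = list(glucose = glucose_step))),
    record_dt = record_dt)
  run_one <- function(cfg) {
    ss0 <- baseline_state(cfg)
    integrate_protocol(prot, cfg, initial = ss0$states)
  }
  list(with_apical_glut2 = run_one(config),
       without_apical_glut2 = run_one(without_apical_glut2(config)))
}

#' Steady-state sweep over luminal glucose
#'
#' @param config a [model_config()].
#' @param glucose_levels luminal glucose grid (mM); published figure uses
#'   0, 20, 50, 80, 100.
#' @param both_variants run with and without apical GLUT2 (default TRUE).
#' @return A `sweep_result` data frame: one row per grid point (and variant),
#'   with steady-state volume, concentrations, potentials and per-pathway
#'   fluxes. The full configuration snapshot is attached as attribute
#'   `config`.
#' @export
run_luminal_sweep <- function(config,
                              glucose_levels = c(0, 20, 50, 80, 100),
                              both_variants = TRUE) {
  variants <- if (both_variants)
    list(with = config, without = without_apical_glut2(config))
  else list(with = config)
  out <- list()
  for (vn in names(variants)) {
    cfg <- variants[[vn]]
    init <- baseline_state(cfg)$states
    for (g in sort(glucose_levels)) {
      ss <- find_steady_state(set_luminal_glucose(cfg, g), initial = init)
      init <- ss$states                       # warm start along the sweep
      out[[length(out) + 1L]] <- cbind(
        data.frame(lumen_glucose_mM = g,
                   apical_glut2 = (vn == "with")), ss_row(ss))
    }
  }
  df <- do.call(rbind, out)
  structure(df, class = c("sweep_result", "data.frame"), config = config)
}

#' Steady-state sweep over one transporter's density
#'
#' One transporter's copy number is scaled by each factor while the other two
#' stay at their reference values, over a grid of luminal glucose levels.
#'
#' @param config a [model_config()].
#' @param transporter `"sglt1"`, `"glut2_apical"` or `"glut2_basolateral"`.
#' @param factors density multipliers (published figure: 0.5 to 1.5).
#' @param glucose_levels luminal glucose grid (mM), published figure 5-50.
#' @return A `sweep_result` data frame with `factor` and `lumen_glucose_mM`
#'   columns.
#' @export
run_density_sweep <- function(config,
                              transporter = c("sglt1", "glut2_apical",
                                              "glut2_basolateral"),
                              factors = c(0.5, 1, 1.5),
                              glucose_levels = c(5, 10, 20, 30, 40, 50)) {
  transporter <- match.arg(transporter)
  out <- list()
  for (f in factors) {
    cfg <- scale_copies(config, transporter, f)
    init <- baseline_state(cfg)$states
    for (g in sort(glucose_levels)) {
      ss <- find_steady_state(set_luminal_glucose(cfg, g), initial = init)
      init <- ss$states
      out[[length(out) + 1L]] <- cbind(
        data.frame(transporter = transporter, factor = f,
                   lumen_glucose_mM = g), ss_row(ss))
    }
  }
  structure(do.call(rbind, out), class = c("sweep_result", "data.frame"),
            config = config)
}

#' Blood-flow and inlet-glucose sweeps
#'
#' First sweep: inlet blood flow from 0.5x to 3x the baseline 1e-17 m^3/s at
#' 50 mM luminal glucose. Second sweep: inlet blood glucose 4-16 mM at
#' baseline flow.
#'
#' @param config a [model_config()] (apical GLUT2 present at baseline count).
#' @param flow_factors multipliers on the baseline blood flow.
#' @param inlet_glucose inlet blood glucose grid (mM).
#' @param lumen_glucose luminal glucose during the sweeps (mM), default 50.
#' @return List of two `sweep_result` data frames: `flow` and `inlet`.
#' @export
run_flow_and_inlet_sweeps <- function(config,
                                      flow_factors = c(0.5, 1, 1.5, 2, 2.5, 3),
                                      inlet_glucose = c(4, 8, 12, 16),
                                      lumen_glucose = 50) {
  cfg50 <- set_luminal_glucose(config, lumen_glucose)
  init <- find_steady_state(cfg50)$states
  q0 <- config$blood_flow
  flow_rows <- list()
  for (f in flow_factors) {
    cfg <- cfg50
    cfg$blood_flow <- q0 * f
    ss <- find_steady_state(cfg, initial = init)
    flow_rows[[length(flow_rows) + 1L]] <- cbind(
      data.frame(flow_factor = f, blood_flow_m3_s = q0 * f), ss_row(ss))
  }
  inlet_rows <- list()
  for (gin in inlet_glucose) {
    cfg <- cfg50
    cfg$blood_inflow$glucose <- gin
    ss <- find_steady_state(cfg, initial = init)
    inlet_rows[[length(inlet_rows) + 1L]] <- cbind(
      data.frame(inlet_glucose_mM = gin), ss_row(ss))
  }
  list(flow = structure(do.call(rbind, flow_rows),
                        class = c("sweep_result", "data.frame"),
                        config = config),
       inlet = structure(do.call(rbind, inlet_rows),
                         class = c("sweep_result", "data.frame"),
                         config = config))
}

#' GLUT2 translocation scenarios
#'
#' Two hypotheses for the origin of apical GLUT2 under a 50 mM glucose
#' stimulus. `"vesicular"`: the basolateral pool stays at its baseline count
#' and apical GLUT2 is added from an intracellular store (fractions are
#' apical/basolateral ratios, published row uses 0.25-1). `"basolateral_swap"`:
#' a fixed total pool (2e8) is split, a fraction moving apically (published
#' fractions 0, 0.2, 0.4, 0.5).
#'
#' @param config a [model_config()].
#' @param mode `"vesicular"` or `"basolateral_swap"`.
#' @param fractions see above; defaults follow the published protocol.
#' @param lumen_glucose stimulus level (mM), default 50.
#' @return A `sweep_result` data frame with the apical/basolateral counts per
#'   row.
#' @export
run_translocation_scenarios <- function(config,
                                        mode = c("basolateral_swap",
                                                 "vesicular"),
                                        fractions = NULL,
                                        lumen_glucose = 50) {
  mode <- match.arg(mode)
  if (is.null(fractions))
    fractions <- if (mode == "vesicular") c(0.25, 0.5, 0.75, 1)
                 else c(0, 0.2, 0.4, 0.5)
  total <- config$glut2_basolateral$n_copies    # 2e8 at baseline
  out <- list()
  for (f in fractions) {
    cfg <- set_luminal_glucose(config, lumen_glucose)
    if (mode == "vesicular") {
      cfg$glut2_apical$n_copies <- f * total
      cfg$glut2_basolateral$n_copies <- total
    } else {
      cfg$glut2_apical$n_copies <- f * total
      cfg$glut2_basolateral$n_copies <- (1 - f) * total
    }
    ss <- find_steady_state(cfg)
    out[[length(out) + 1L]] <- cbind(
      data.frame(mode = mode, fraction = f,
                 n_apical = cfg$glut2_apical$n_copies,
                 n_basolateral = cfg$glut2_basolateral$n_copies), ss_row(ss))
  }
  structure(do.call(rbind, out), class = c("sweep_result", "data.frame"),
            config = config)
}

#' Short-term SGLT1 upregulation scenarios
#'
#' Five scenarios at 50 mM luminal glucose: (A) baseline SGLT1, no apical
#' GLUT2; (B) 1.5x SGLT1, apical GLUT2 = 0.5x basolateral; (C) baseline
#' SGLT1, apical GLUT2 = basolateral; (D) 2x SGLT1, apical GLUT2 = 0.5x
#' basolateral; (E) 2x SGLT1, no apical GLUT2.
#'
#' @param config a [model_config()].
#' @param lumen_glucose stimulus level (mM), default 50.
#' @return data.frame with one row per scenario: blood and cell glucose and
#'   the basolateral glucose flux (positive into the blood).
#' @export
run_sglt1_scenarios <- function(config, lumen_glucose = 50) {
  nbl <- config$glut2_basolateral$n_copies
  scen <- list(A = c(sglt1 = 1.0, ap = 0),
               B = c(sglt1 = 1.5, ap = 0.5),
               C = c(sglt1 = 1.0, ap = 1.0),
               D = c(sglt1 = 2.0, ap = 0.5),
               E = c(sglt1 = 2.0, ap = 0))
  out <- list()
  for (nm in names(scen)) {
    cfg <- set_luminal_glucose(config, lumen_glucose)
    cfg <- scale_copies(cfg, "sglt1", scen[[nm]][["sglt1"]])
    cfg$glut2_apical$n_copies <- scen[[nm]][["ap"]] * nbl
    ss <- find_steady_state(cfg)
    out[[length(out) + 1L]] <- data.frame(
      scenario = nm,
      sglt1_factor = scen[[nm]][["sglt1"]],
      apical_to_basolateral = scen[[nm]][["ap"]],
      blood_glucose_mM = ss$states$blood$glucose,
      cell_glucose_mM = ss$states$cell$glucose,
      flux_to_blood_mol_s = -ss$fluxes$glut2_basolateral,
      converged = ss$converged)
  }
  structure(do.call(rbind, out), class = c("sweep_result", "data.frame"),
            config = config)
}

#' Perfused intestinal loop protocol
#'
#' Steady-state absorption rates of glucose, sodium and water for the
#' dog-loop infusate (90 mM NaCl, 100 mM glucose, 6 mM K+ in the lumen) at
#' three inlet blood flows spanning the experimental uncertainty, scaled from
#' one cell to the whole loop. Transporter counts follow the published
#' protocol (apical and basolateral GLUT2 2e9, SGLT1 1e8); inflowing blood
#' uses literature ion values.
#'
#' @param config a [model_config()].
#' @param inlet_flows per-cell inlet blood flows (m^3/s).
#' @param anatomy an [anatomy_params()]; the published segment cell count
#'   scales per-cell rates to the loop.
#' @return data.frame: one row per flow with loop-level absorption of
#'   glucose and Na+ (umol/min) and water (ml/min), positive into the blood.
#' @export
run_collin_loop <- function(config,
                            inlet_flows = c(6e-18, 1e-17, 3e-17),
                            anatomy = anatomy_params()) {
  cfg <- config
  cfg$lumen <- list(na = 90, k = 6, cl = 96, hco3 = 0, glucose = 100,
                    ph = 7.4)
  cfg$blood_inflow <- list(na = 140, k = 4.5, cl = 102, hco3 = 24,
                           glucose = 5, ph = 7.4)
  cfg$sglt1$n_copies <- 1e8
  cfg$glut2_apical$n_copies <- 2e9
  cfg$glut2_basolateral$n_copies <- 2e9
  ncells <- anatomy$cell_count
  out <- list()
  init <- NULL
  for (q in sort(inlet_flows)) {
    cfg$blood_flow <- q
    ss <- find_steady_state(cfg, initial = init)
    init <- ss$states
    fl <- ss$fluxes
    tb <- ss$fluxes$channels
    # into-blood rates per cell: basolateral transcellular + paracellular
    glc <- -fl$glut2_basolateral
    na  <- -(fl$pump[["na"]] + tb$bl_na) + tb$pc_na
    h2o <- -fl$water_basolateral + fl$water_paracellular
    out[[length(out) + 1L]] <- data.frame(
      inlet_flow_m3_s = q,
      glucose_umol_min = glc * ncells * 60 * 1e6,
      sodium_umol_min = na * ncells * 60 * 1e6,
      water_ml_min = h2o * ncells * 60 * 1e6,   # m^3 -> ml
      converged = ss$converged)
  }
  structure(do.call(rbind, out), class = c("sweep_result", "data.frame"),
            config = cfg)
}

#' Steady states of the glucose-step endpoint (published steady-state table)
#'
#' Steady state at 50 mM luminal glucose for the model with and without
#' apical GLUT2, reported in the layout of the published table.
#'
#' @param config a [model_config()].
#' @param lumen_glucose luminal glucose (mM), default 50.
#' @return data.frame with variables as rows and the two model variants as
#'   columns.
#' @export
run_table3 <- function(config = model_config(), lumen_glucose = 50) {
  sswo <- find_steady_state(
    set_luminal_glucose(without_apical_glut2(config), lumen_glucose))
  sswi <- find_steady_state(set_luminal_glucose(config, lumen_glucose))
  col <- function(ss) {
    st <- ss$states$cell
    c(round(st$na, 1), round(st$k, 1), round(st$cl, 1),
      round(ss$v_apical, 1), round(ss$v_basolateral, 1), round(st$ph, 2))
  }
  data.frame(
    variable = c("Na+ (mM)", "K+ (mM)", "Cl- (mM)",
                 "Apical (lumen-cell) membrane potential (mV)",
                 "Basolateral (interstitium-cell) membrane potential (mV)",
                 "pH"),
    no_apical_glut2 = col(sswo),
    with_apical_glut2 = col(sswi))
}
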