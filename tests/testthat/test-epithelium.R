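# Three-compartment assembly: osmolarity, current balance, governing
# equations, conservation laws.

test_that("compute_osmolarity is a direct solute sum (plus impermeants for the cell)", {
  lum <- make_state(150, 5, 150, role = "lumen")
  expect_identical(compute_osmolarity(lum), 305)
  empty <- make_state(0, 0, 0, volume = 1e-15, role = "lumen")
  expect_identical(compute_osmolarity(empty), 0)
  set.seed(21)
  cfg <- model_config()
  for (rep in 1:10) {
    v <- runif(1, 5e-16, 2e-15)
    x <- runif(5, 0, 150)
    st <- compartment_state(x[1], x[2], x[3], x[4], x[5], volume = v,
                            role = "cell")
    expect_equal(compute_osmolarity(st, cfg),
                 sum(x) + cfg$osmolytes$amount / v, tolerance = 1e-12)
    # without a config the impermeant pool is not counted
    expect_equal(compute_osmolarity(st), sum(x), tolerance = 1e-12)
  }
})

test_that("membrane potentials zero the current balance to solver precision", {
  cfg <- model_config()
  st <- initial_states(cfg)
  pot <- membrane_potentials(st$lumen, st$cell, st$blood, cfg)
  # residual relative to the largest single membrane current
  i_scale <- 96485.33212 *
    max(abs(unlist(compute_fluxes(st$lumen, st$cell, st$blood,
                                  pot$v_apical, pot$v_basolateral,
                                  cfg)$channels)))
  expect_lt(max(abs(pot$residual)), 1e-10 * i_scale)
  expect_true(pot$v_apical < 0 && pot$v_basolateral < 0)
})

test_that("symmetric membranes and baths give equal apical and basolateral potentials", {
  cfg <- make_fixture("symmetric-membranes")
  st <- initial_states(cfg)
  pot <- membrane_potentials(st$lumen, st$cell, st$blood, cfg)
  expect_equal(pot$v_apical, pot$v_basolateral, tolerance = 1e-6)
})

test_that("dead network yields zero derivatives everywhere", {
  cfg <- make_fixture("dead-network")
  st <- initial_states(cfg)
  st$cell <- compartment_state(150, 5, 150, hco3 = 0, glucose = 4, ph = 7.4,
                               volume = 1e-15, role = "cell")
  cfg$osmolytes$amount <- 0
  y <- enterosim:::pack_states(st, cfg)
  out <- model_rhs(y, cfg)
  expect_true(all(abs(out$dy) < 1e-25))
})

test_that("cell charge (including impermeant valence) is conserved along trajectories", {
  cfg <- model_config()
  st <- initial_states(cfg)
  y0 <- enterosim:::pack_states(st, cfg)
  charge <- function(y) sum(c(1, 1, -1, -1, 0) * y[1:5]) +
    cfg$osmolytes$valence * cfg$osmolytes$amount
  prot <- protocol(300, events = list(list(time = 0, lumen = list(glucose = 30))),
                   record_dt = 50)
  tr <- integrate_protocol(prot, cfg, initial = st)
  yT <- attr(tr, "final_y")
  # drift relative to the total cation amount
  expect_lt(abs(charge(yT) - charge(y0)) / abs(y0[[1]] + y0[[2]]), 1e-6)
})

test_that("closed variant conserves species amounts (finite lumen, no blood flow)", {
  cfg <- model_config()
  cfg$lumen_finite <- TRUE
  cfg$lumen_volume <- 5e-15
  cfg$lumen$glucose <- 20
  cfg$blood_flow <- 0
  # close the water route into the fixed-volume blood compartment, whose
  # outflow would otherwise carry solutes out of the closed system
  cfg$water$basolateral <- water_params(0, "basolateral")
  cfg$water$paracellular <- water_params(0, "paracellular")
  st <- initial_states(cfg)
  y0 <- enterosim:::pack_states(st, cfg)
  totals <- function(y) {
    cell <- y[1:5]
    blood <- y[8:12] * cfg$blood_volume
    lum <- y[14:18]
    cell + blood + lum
  }
  prot <- protocol(200, events = list(list(time = 0)), record_dt = 50)
  tr <- integrate_protocol(prot, cfg, initial = st)
  yT <- attr(tr, "final_y")
  t0 <- totals(y0); tT <- totals(yT)
  for (i in 1:5) {
    if (t0[i] > 0) expect_lt(abs(tT[i] - t0[i]) / t0[i], 1e-8)
  }
})

test_that("blood compartment washes out to the inflow composition without transport", {
  cfg <- make_fixture("dead-network")
  # reopen flow, keep transport off; blood starts away from the inflow value
  st <- initial_states(cfg)
  st$blood <- compartment_state(120, 8, 120, hco3 = 0, glucose = 9, ph = 7.4,
                                volume = cfg$blood_volume, role = "blood")
  prot <- protocol(200, events = list(list(time = 0)), record_dt = 50)
  tr <- integrate_protocol(prot, cfg, initial = st)
  n <- nrow(tr)
  # V/Q = 10 s: after 200 s the deviation is e^-20 of the start
  expect_equal(tr$blood_glucose_mM[n], cfg$blood_inflow$glucose,
               tolerance = 1e-6)
  expect_equal(tr$blood_na_mM[n], cfg$blood_inflow$na, tolerance = 1e-6)
  # with no water flux the outlet flow equals the inlet flow: q_out - q_in = 0
  out <- model_rhs(attr(tr, "final_y"), cfg)
  expect_equal(out$q_out, cfg$blood_flow, tolerance = 1e-12)
})

test_that("steady state closes every species and the water balance", {
  cfg <- set_luminal_glucose(model_config(), 50)
  ss <- find_steady_state(cfg)
  expect_true(ss$converged)
  fl <- ss$fluxes
  # apical water flux equals basolateral water flux (transcellular stream)
  expect_equal(fl$water_apical, -fl$water_basolateral, tolerance = 1e-6)
  # glucose closure: SGLT1 + apical GLUT2 + basolateral GLUT2 sum to zero
  jmax <- max(abs(c(fl$sglt1[["glucose"]], fl$glut2_apical,
                    fl$glut2_basolateral)))
  expect_lt(abs(fl$sglt1[["glucose"]] + fl$glut2_apical +
                fl$glut2_basolateral), 1e-6 * jmax)
})

test_that("raising luminal glucose shrinks the cell at steady state (no apical GLUT2)", {
  cfg <- without_apical_glut2(model_config())
  ss0 <- find_steady_state(set_luminal_glucose(cfg, 0))
  ss50 <- find_steady_state(set_luminal_glucose(cfg, 50), initial = ss0$states)
  ss100 <- find_steady_state(set_luminal_glucose(cfg, 100),
                             initial = ss50$states)
  v <- c(ss0$states$cell$volume, ss50$states$cell$volume,
         ss100$states$cell$volume)
  expect_true(all(diff(v) < 0))
})

test_that("negative outlet blood flow is a configuration error", {
  cfg <- model_config()
  cfg$blood_flow <- 0
  cfg$lumen$glucose <- 100           # strong water secretion, no inlet flow
  cfg$water$paracellular <- water_params(1e-17, "paracellular")
  st <- initial_states(cfg)
  y <- enterosim:::pack_states(st, cfg)
  expect_error(model_rhs(y, cfg), "outlet blood flow")
})
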