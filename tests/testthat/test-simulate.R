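# Protocol integration and steady-state location.

test_that("a zero-length protocol returns only the initial state", {
  cfg <- model_config()
  prot <- protocol(0, events = list(list(time = 0)))
  tr <- integrate_protocol(prot, cfg)
  expect_equal(nrow(tr), 1L)
  expect_identical(tr$time_s, 0)
  st <- initial_states(cfg)
  expect_equal(tr$cell_na_mM, st$cell$na, tolerance = 1e-12)
})

test_that("luminal composition switches exactly at the scheduled event time", {
  cfg <- model_config()
  prot <- protocol(400, events = list(
    list(time = 0, lumen = list(glucose = 0)),
    list(time = 200, lumen = list(glucose = 50))), record_dt = 50)
  tr <- integrate_protocol(prot, cfg)
  # the event time carries two rows: the end of the old segment and the start
  # of the new one -- the discontinuity is never interpolated through
  expect_true(all(tr$lumen_glucose_mM[tr$time_s < 200] == 0))
  expect_true(all(tr$lumen_glucose_mM[tr$time_s > 200] == 50))
  at_event <- tr$lumen_glucose_mM[tr$time_s == 200]
  expect_setequal(at_event, c(0, 50))
  # the step is seen by the fluxes: SGLT1 flux jumps exactly at the event
  j_before <- tr$sglt1_glucose_mol_s[tr$time_s == 200 &
                                     tr$lumen_glucose_mM == 0]
  j_after <- tr$sglt1_glucose_mol_s[tr$time_s == 200 &
                                    tr$lumen_glucose_mM == 50]
  expect_gt(j_after, 10 * max(j_before, 1e-25))
})

test_that("repeated runs are bit-identical (deterministic pipeline)", {
  cfg <- model_config()
  prot <- protocol(300, events = list(list(time = 0, lumen = list(glucose = 20))),
                   record_dt = 100)
  tr1 <- integrate_protocol(prot, cfg)
  tr2 <- integrate_protocol(prot, cfg)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  ss1 <- find_steady_state(cfg)
  ss2 <- find_steady_state(cfg)
  expect_identical(ss1$y, ss2$y)
})

test_that("halving the solver tolerance changes the final state by < 0.1%", {
  cfg <- set_luminal_glucose(model_config(), 30)
  st <- initial_states(cfg)
  prot <- protocol(500, events = list(list(time = 0)), record_dt = 250)
  t1 <- integrate_protocol(prot, cfg, initial = st, rtol = 1e-5)
  t2 <- integrate_protocol(prot, cfg, initial = st, rtol = 5e-6)
  y1 <- attr(t1, "final_y"); y2 <- attr(t2, "final_y")
  sc <- enterosim:::solver_scales(y1)
  expect_lt(max(abs(y1 - y2) / sc), 1e-3)
})

test_that("find_steady_state is a fixed point and is initial-condition independent", {
  cfg <- set_luminal_glucose(model_config(), 50)
  ss <- find_steady_state(cfg)
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-9)
  # restarting from the converged state returns it unchanged
  ss2 <- find_steady_state(cfg, initial = ss$states)
  for (fld in c("na", "k", "cl", "glucose", "volume"))
    expect_equal(ss2$states$cell[[fld]], ss$states$cell[[fld]],
                 tolerance = 1e-6)
  # a different physiological start converges to the same point (multi-start).
  # The flow conserves cell charge and the inert HCO3-/H+ amounts, so the
  # alternative start must lie on the same invariant manifold: same amounts of
  # charge, HCO3- and H+, different volume and Na/K/Cl/glucose split.
  st0 <- initial_states(cfg)
  v0 <- st0$cell$volume; v1 <- 1.2 * v0
  hco3_1 <- st0$cell$hco3 * v0 / v1
  q0 <- (st0$cell$na + st0$cell$k - st0$cell$cl - st0$cell$hco3) * v0
  na1 <- st0$cell$na + 10; k1 <- st0$cell$k - 10
  cl1 <- na1 + k1 - hco3_1 - q0 / v1
  ph1 <- st0$cell$ph + log10(v1 / v0)
  alt <- ss$states
  alt$cell <- compartment_state(na1, k1, cl1, hco3 = hco3_1, glucose = 8,
                                ph = ph1, volume = v1, role = "cell")
  alt$blood <- compartment_state(140, 6, 140, hco3 = 0, glucose = 7, ph = 7.4,
                                 volume = cfg$blood_volume, role = "blood")
  ss3 <- find_steady_state(cfg, initial = alt)
  expect_true(ss3$converged)
  for (fld in c("na", "k", "cl", "glucose"))
    expect_equal(ss3$states$cell[[fld]], ss$states$cell[[fld]],
                 tolerance = 5e-3)
  expect_equal(ss3$states$cell$volume, ss$states$cell$volume, tolerance = 5e-3)
})

test_that("protocol validation rejects malformed schedules", {
  expect_error(protocol(10, events = list(list(time = 5))), "first event")
  expect_error(protocol(10, events = list(list(time = 0), list(time = 0))),
               "strictly increasing")
  expect_error(protocol(1, events = list(list(time = 0), list(time = 5))),
               "t_end")
})
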