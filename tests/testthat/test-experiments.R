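# Scenario runners: structural checks that are cheap enough for the unit
# suite. The quantitative reproductions of the published tables and figures
# live in test-acceptance.R.

test_that("equivalent-MM table is well formed and Km tracks intracellular glucose", {
  t1 <- run_table1(gi_levels = c(2, 30))
  expect_identical(nrow(t1), 2L)
  expect_true(all(t1$sglt1_vmax_umol_min_cm > 0 & t1$glut2_km_mM > 0))
  # SGLT1 equivalent Km is insensitive to trans glucose; GLUT2's grows with it
  expect_lt(abs(t1$sglt1_km_mM[2] - t1$sglt1_km_mM[1]), 0.2)
  expect_gt(t1$glut2_km_mM[2], 2.5 * t1$glut2_km_mM[1])
  # SGLT1 equivalent Vmax falls with trans glucose (product inhibition)
  expect_lt(t1$sglt1_vmax_umol_min_cm[2], t1$sglt1_vmax_umol_min_cm[1])
})

test_that("a transporter scaled to zero density carries exactly zero flux", {
  sw <- run_density_sweep(model_config(), "glut2_apical", factors = c(0, 1),
                          glucose_levels = 20)
  expect_identical(sw$glut2_apical_mol_s[sw$factor == 0], 0)
  expect_true(abs(sw$glut2_apical_mol_s[sw$factor == 1]) > 0)
})

test_that("translocation fraction 0 reproduces the no-apical-GLUT2 baseline exactly", {
  cfg <- model_config()
  tr <- run_translocation_scenarios(cfg, "basolateral_swap", fractions = 0)
  ref_cfg <- set_luminal_glucose(without_apical_glut2(cfg), 50)
  ref <- find_steady_state(ref_cfg)
  expect_equal(tr$cell_glucose_mM, ref$states$cell$glucose, tolerance = 1e-6)
  expect_equal(tr$blood_glucose_mM, ref$states$blood$glucose, tolerance = 1e-6)
  expect_identical(tr$n_apical, 0)
  expect_identical(tr$n_basolateral, 2e8)
})

test_that("sweeps re-converge to the same answer from warm and cold starts", {
  cfg <- model_config()
  sw <- run_luminal_sweep(cfg, glucose_levels = c(20, 50),
                          both_variants = FALSE)       # warm-started chain
  cold <- find_steady_state(set_luminal_glucose(cfg, 50))  # cold start
  warm_row <- sw[sw$lumen_glucose_mM == 50, ]
  expect_lt(abs(warm_row$cell_glucose_mM - cold$states$cell$glucose) /
            cold$states$cell$glucose, 5e-3)
  expect_lt(abs(warm_row$cell_volume_m3 - cold$states$cell$volume) /
            cold$states$cell$volume, 5e-3)
})

test_that("perfused-loop absorption rates are positive and linear in cell count", {
  cfg <- model_config()
  an1 <- anatomy_params()
  res1 <- run_collin_loop(cfg, inlet_flows = 1e-17, anatomy = an1)
  expect_true(res1$converged)
  expect_gt(res1$glucose_umol_min, 0)
  expect_gt(res1$sodium_umol_min, 0)
  expect_gt(res1$water_ml_min, 0)
  an2 <- anatomy_params(cell_count = 2 * an1$cell_count)
  res2 <- run_collin_loop(cfg, inlet_flows = 1e-17, anatomy = an2)
  expect_equal(res2$glucose_umol_min, 2 * res1$glucose_umol_min,
               tolerance = 1e-9)
  expect_equal(res2$water_ml_min, 2 * res1$water_ml_min, tolerance = 1e-9)
})

test_that("SGLT1-upregulation scenario table has the expected layout and signs", {
  tab <- run_sglt1_scenarios(model_config())
  expect_identical(tab$scenario, c("A", "B", "C", "D", "E"))
  expect_true(all(tab$converged))
  expect_true(all(tab$flux_to_blood_mol_s > 0))
  # more SGLT1 with no apical GLUT2 (E vs A) raises cell glucose
  expect_gt(tab$cell_glucose_mM[tab$scenario == "E"],
            tab$cell_glucose_mM[tab$scenario == "A"])
})
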