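# Anatomical scaling helpers.

test_that("cell count estimate follows the geometric chain (arithmetic oracle)", {
  an <- anatomy_params()
  est <- estimate_cell_count(an)
  # independent spreadsheet-style recomputation
  tube_mm2 <- pi * 10 * 750                 # 1 cm diameter, 75 cm length
  villi <- 23 * tube_mm2
  villus_um2 <- pi * 400 * 750
  cells <- villi * villus_um2 / 42
  expect_equal(est$cell_count, cells, tolerance = 1e-12)
  expect_equal(est$intermediates$mucosa_mass_g, 0.35 * 75, tolerance = 1e-12)
  # doubling villus density doubles the count
  an2 <- anatomy_params(villi_per_mm2 = 46)
  expect_equal(estimate_cell_count(an2)$cell_count, 2 * cells,
               tolerance = 1e-12)
  # the geometric estimate disagrees with the published count by design
  expect_gt(est$cell_count / est$cell_count_published, 5)
})

test_that("per-cell blood volume and flow fall in the published brackets", {
  est <- estimate_cell_count(anatomy_params())
  expect_gte(est$per_cell_blood_volume_m3, 1e-16 * 0.9)
  expect_lte(est$per_cell_blood_volume_m3, 4e-16)
  expect_true(all(est$per_cell_blood_flow_m3_s >= 1e-17 * 0.9))
  expect_true(all(est$per_cell_blood_flow_m3_s <= 4.6e-17))
})

test_that("per-cm scaling is linear in copy number and inverts exactly", {
  an <- anatomy_params()
  j <- 3e-24
  expect_identical(per_cm_scaling(0, 3e7, an), 0)
  expect_equal(per_cm_scaling(j, 6e7, an), 2 * per_cm_scaling(j, 3e7, an),
               tolerance = 1e-14)
  # round-trip per-cm -> per-transporter -> per-cm is the identity
  f_cm <- per_cm_scaling(j, 3e7, an)
  expect_equal(per_cell_scaling(f_cm, 3e7, an), j, tolerance = 1e-14)
  # explicit cells_per_cm overrides the anatomy-derived default
  expect_equal(per_cm_scaling(j, 3e7, an, cells_per_cm = 2 * 1.3e9 / 75),
               2 * f_cm, tolerance = 1e-14)
})

test_that("anatomy validation rejects non-positive measurements", {
  expect_error(anatomy_params(villus_height_mm = 0), "> 0")
  expect_error(anatomy_params(segment_length_cm = -1), "> 0")
})
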