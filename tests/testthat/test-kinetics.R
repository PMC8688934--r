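# Per-transporter flux laws: the 6-state SGLT1 cycle, the GLUT2 carrier,
# the Na/K pump, GHK channels and osmotic water flux.

test_that("SGLT1 occupancy solve matches King-Altman and master-equation oracles", {
  set.seed(42)
  for (rep in 1:20) {
    p <- random_sglt1()
    na_o <- runif(1, 50, 200); glc_o <- runif(1, 0.5, 100)
    na_i <- runif(1, 5, 80); glc_i <- runif(1, 0.1, 60)
    v <- runif(1, -90, 10)
    occ <- sglt1_occupancy(na_o, glc_o, na_i, glc_i, v, p)
    expect_true(all(occ$p >= -1e-12))
    expect_equal(sum(occ$p), 1, tolerance = 1e-12)
    rv <- sglt1_rate_vectors(p, na_o, glc_o, na_i, glc_i, v)
    expect_equal(occ$p, ka_occupancy(rv$fw, rv$bw), tolerance = 1e-9)
  }
  # relaxation oracle (expensive: a few cases)
  set.seed(7)
  for (rep in 1:3) {
    p <- random_sglt1()
    occ <- sglt1_occupancy(150, 10, 40, 5, -65, p)
    rv <- sglt1_rate_vectors(p, 150, 10, 40, 5, -65)
    expect_equal(occ$p, relax_occupancy(rv$fw, rv$bw), tolerance = 1e-10)
  }
})

test_that("SGLT1 flux respects substrate zeros, stoichiometry and monotonicity", {
  p <- sglt1_params()
  lum0 <- make_state(150, 5, 150, glucose = 0, role = "lumen")
  cell0 <- make_state(40, 95, 45, glucose = 0)
  expect_identical(sglt1_flux(lum0, cell0, -65, p)[["glucose"]], 0)

  set.seed(11)
  prev <- -Inf
  for (g in c(0.5, 2, 10, 30, 80)) {
    lum <- make_state(150, 5, 150, glucose = g, role = "lumen")
    cell <- make_state(40, 95, 45, glucose = 12)
    j <- sglt1_flux(lum, cell, -65, p)
    expect_identical(j[["na"]], 2 * j[["glucose"]])   # exact 2:1 coupling
    expect_gte(j[["glucose"]], prev)
    prev <- j[["glucose"]]
  }
  # random states keep exact stoichiometry
  for (rep in 1:10) {
    lum <- make_state(runif(1, 80, 200), 5, 150, glucose = runif(1, 0, 100),
                      role = "lumen")
    cell <- make_state(runif(1, 10, 80), 95, 45, glucose = runif(1, 0, 60))
    j <- sglt1_flux(lum, cell, runif(1, -90, 0), p)
    expect_identical(j[["na"]], 2 * j[["glucose"]])
    expect_gte(j[["glucose"]], 0)                     # reverse clamp
  }
})

test_that("SGLT1 cycle satisfies the thermodynamic equilibrium condition", {
  # At V = 0 and equal compositions on both faces there is no driving force:
  # the cycle must carry no net flux (detailed balance built into k16).
  set.seed(5)
  for (rep in 1:10) {
    p <- random_sglt1()
    occ <- sglt1_occupancy(100, 20, 100, 20, 0, p)
    scale <- p$rates[["k34"]]   # compare against a forward one-way rate
    expect_lt(abs(occ$cycle_rate), 1e-10 * scale)
  }
  # supplying an inconsistent k16 is rejected
  expect_error(sglt1_params(k16 = 1), "thermodynamic")
})

test_that("GLUT2 carrier is passive, saturating and antisymmetric when symmetric", {
  p <- carrier_params()
  expect_lt(abs(glut2_flux(10, 10, p)), 1e-25)        # equilibrium
  expect_lt(abs(glut2_flux(0, 0, p)), 1e-30)
  # monotone nondecreasing in cis substrate, trans fixed
  j <- vapply(c(0, 1, 5, 20, 50, 100), function(s) glut2_flux(s, 10, p),
              numeric(1))
  expect_true(all(diff(j) > 0))
  # saturating: doubling substrate far above Km gains little
  gain <- glut2_flux(400, 0, p) / glut2_flux(200, 0, p)
  expect_lt(gain, 1.25)
  # antisymmetry under parameter-symmetric carriers, on a grid
  set.seed(3)
  for (rep in 1:5) {
    ps <- random_carrier(symmetric = TRUE)
    for (a in c(0, 2, 17, 60)) for (b in c(1, 8, 45)) {
      expect_equal(glut2_flux(a, b, ps), -glut2_flux(b, a, ps),
                   tolerance = 1e-12)
    }
  }
  # passive equilibrium for random asymmetric carriers too
  for (rep in 1:10) {
    pa <- random_carrier()
    cc <- runif(1, 0.1, 80)
    expect_lt(abs(glut2_flux(cc, cc, pa)), 1e-26)   # ~1e-8 of typical flux
  }
  expect_error(glut2_flux(-1, 5, p), "concentrations")
})

test_that("pump law has exact 3:2 stoichiometry, saturation and Hill form", {
  p <- pump_params(k_max = 50, km_na = 20, km_k = 1.5, n_copies = 1e6)
  cell0 <- make_state(0, 120, 40)
  bath <- make_state(150, 5, 150, role = "blood")
  expect_identical(pump_flux(cell0, bath, p), c(na = 0, k = 0))
  # saturation limit: n_copies * k_max * stoichiometric coefficient
  cell_sat <- make_state(5e4, 100, 40)
  bath_sat <- make_state(150, 5e4, 150, role = "blood")
  j <- pump_flux(cell_sat, bath_sat, p)
  expect_equal(j[["na"]], -3 * 1e6 * 50 / 6.02214076e23, tolerance = 1e-3)
  expect_equal(j[["k"]], 2 * 1e6 * 50 / 6.02214076e23, tolerance = 1e-3)
  # direct-formula oracle on 100 random states; ratio exactly 3:-2
  set.seed(9)
  for (rep in 1:100) {
    nai <- runif(1, 1, 120); ko <- runif(1, 0.5, 12)
    cell <- make_state(nai, 100, 40)
    bth <- make_state(140, ko, 120, role = "blood")
    j <- pump_flux(cell, bth, p)
    direct <- 1e6 * 50 * (nai / (nai + 20))^3 * (ko / (ko + 1.5))^2 /
      6.02214076e23
    expect_equal(j[["k"]], 2 * direct, tolerance = 1e-12)
    expect_identical(2 * j[["na"]], -3 * j[["k"]])   # exact 3:2 stoichiometry
    expect_lte(j[["na"]], 0)
    expect_gte(j[["k"]], 0)
  }
  # monotone in both substrates
  f_na <- vapply(c(5, 20, 60, 100), function(x)
    pump_flux(make_state(x, 100, 40), bath, p)[["k"]], numeric(1))
  expect_true(all(diff(f_na) > 0))
  f_k <- vapply(c(0.5, 2, 5, 10), function(x)
    pump_flux(make_state(40, 100, 40), make_state(140, x, 120, role = "blood"),
              p)[["k"]], numeric(1))
  expect_true(all(diff(f_k) > 0))
})

test_that("GHK flux has the correct limits and reverses at the Nernst potential", {
  p <- channel_params(2e-18, +1, "basolateral")
  expect_identical(ghk_flux(10, 10, 0, p), 0)
  # v -> 0 limit equals P*A*(c_out - c_in) within 0.1%
  for (v in c(-0.009, -0.001, 0.001, 0.009)) {
    expect_equal(ghk_flux(30, 90, v, p), 2e-18 * (90 - 30), tolerance = 1e-3)
  }
  # sign change exactly at the Nernst potential (root-finding oracle)
  rtf <- 8.314462618 * 310.15 / 96485.33212 * 1e3    # mV
  for (z in c(-1, 1)) {
    pz <- channel_params(1e-18, z, "apical")
    c_in <- 15; c_out <- 120
    root <- uniroot(function(v) ghk_flux(c_in, c_out, v, pz),
                    interval = c(-150, 150), tol = 1e-12)$root
    expect_equal(root, rtf / z * log(c_out / c_in), tolerance = 1e-6)
  }
  # flux into "in" is positive when the electrochemical gradient points in
  expect_gt(ghk_flux(15, 120, -60, channel_params(1e-18, 1, "apical")), 0)
})

test_that("osmotic water flux is linear in the osmotic difference", {
  w <- water_params(2e-19, "apical")
  expect_identical(water_flux(300, 300, w), 0)
  j1 <- water_flux(300, 320, w)
  j2 <- water_flux(300, 340, w)
  expect_gt(j1, 0)                      # towards the hyperosmolar side
  expect_equal(j2, 2 * j1, tolerance = 1e-12)
  # hyperosmolar lumen draws water out of the cell across the apical membrane
  lum <- make_state(150, 5, 150, glucose = 100, role = "lumen")
  cell <- make_state(50, 95, 45, hco3 = 25, glucose = 10)
  expect_lt(water_flux(lum, cell, w), 0)
  # reflection coefficients: a fully reflected solute stops driving flux
  w0 <- water_params(2e-19, "apical",
                     sigma = c(na = 1, k = 1, cl = 1, hco3 = 1, glucose = 0))
  lum_iso <- make_state(50, 95, 45, hco3 = 25, glucose = 100, role = "lumen")
  expect_identical(water_flux(lum_iso, cell, w0), 0)
})

test_that("parameter constructors validate their domains", {
  expect_error(sglt1_params(k12 = -1), "rate constants")
  expect_error(sglt1_params(n_copies = -5), "n_copies")
  expect_error(carrier_params(k_tl_oi = 0), "rate constants")
  expect_error(channel_params(1e-18, 2, "apical"), "valence")
  expect_error(channel_params(-1e-18, 1, "apical"), "p_area")
  expect_error(water_params(-1, "apical"), "lp")
  expect_error(water_params(1e-19, "apical",
                            sigma = c(na = 2, k = 1, cl = 1, hco3 = 1,
                                      glucose = 1)), "reflection")
  expect_error(compartment_state(-5, 5, 5), "concentrations")
})
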