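# Equivalent Michaelis-Menten fitting.

test_that("noise-free curves are recovered to 6 digits", {
  s <- seq(1, 100, by = 5)
  fit <- fit_michaelis_menten(s, 1 * s / (5 + s))
  expect_equal(fit$v_max, 1, tolerance = 1e-6)
  expect_equal(fit$k_m, 5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # methods behave like a fitted-model object
  expect_named(coef(fit), c("v_max", "k_m"))
  expect_equal(predict(fit, newdata = 5), 0.5, tolerance = 1e-6)
  expect_equal(unname(residuals(fit)), rep(0, length(s)), tolerance = 1e-7)
})

test_that("fit residual matches a brute-force grid search within 1%", {
  set.seed(13)
  s <- seq(0, 100, by = 5)
  j <- 0.8 * s / (12 + s) + rnorm(length(s), sd = 0.02)
  fit <- fit_michaelis_menten(s, j)
  grid_v <- seq(0.5 * fit$v_max, 1.5 * fit$v_max, length.out = 120)
  grid_k <- seq(0.5 * fit$k_m, 1.5 * fit$k_m, length.out = 120)
  rss_grid <- min(outer(grid_v, grid_k, Vectorize(function(v, km)
    sum((j - v * s / (km + s))^2))))
  expect_lte(fit$rss, rss_grid * 1.01)
})

test_that("degenerate inputs raise fit-failure errors", {
  expect_error(fit_michaelis_menten(c(1, 2), c(0.1, 0.2)), ">= 3 distinct")
  expect_error(fit_michaelis_menten(c(1, 1, 1), c(0.1, 0.1, 0.1)), "distinct")
  expect_error(fit_michaelis_menten(c(-1, 2, 5), c(0.1, 0.2, 0.3)), ">= 0")
  expect_error(fit_michaelis_menten(c(1, 2, 5), c(-0.3, -0.2, -0.1)),
               "no positive branch")
})

test_that("fits survive curves with a negative branch (trans-dominated carrier)", {
  s <- seq(0, 100, by = 5)
  j <- (s - 30) / (40 + 4 * s)      # saturating curve, negative below 30
  fit <- fit_michaelis_menten(s, j)
  expect_gt(fit$v_max, 0)
  expect_gt(fit$k_m, 0)
})
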