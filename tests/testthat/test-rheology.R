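test_that("yield stress follows the cubic hematocrit law", {
  expect_identical(yield_stress(0), 0)
  # direct evaluation of (0.625 H)^3
  expect_equal(yield_stress(0.45), 0.28125^3, tolerance = 1e-15)
  expect_equal(yield_stress(0.45), 0.022247314453125)
  expect_equal(yield_stress(0.35), 0.010467529296875)
  H <- seq(0, 0.9, by = 0.01)
  expect_true(all(diff(yield_stress(H)) > 0))
  expect_error(yield_stress(1), "hematocrit")
  expect_error(yield_stress(-0.1), "hematocrit")
})

test_that("casson viscosity has the right limits and shape", {
  rh <- rheology_params(H = 0.45)
  g <- 10^seq(-8, 5, length.out = 200)
  mu <- casson_viscosity(g, rh)
  # continuity at zero shear: matches the m-limit closed form
  mu0 <- 0.1 * (sqrt(rh$eta) + sqrt(rh$tau_y * rh$m))^2
  expect_equal(casson_viscosity(0, rh), mu0, tolerance = 1e-12)
  expect_equal(casson_viscosity(1e-8, rh), mu0, tolerance = 1e-6)
  # infinite-shear plateau 0.1 eta
  expect_equal(casson_viscosity(1e9, rh), 0.1 * rh$eta, tolerance = 1e-4)
  # strictly decreasing, bounded by mu(0)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu <= mu0 + 1e-15))
  # yield-free fluid is Newtonian at every shear rate
  rh0 <- rheology_params(H = 0)
  expect_equal(casson_viscosity(g, rh0), rep(0.1 * rh0$eta, length(g)))
  # newtonian switch overrides H
  rhn <- rheology_params(H = 0.45, newtonian = TRUE)
  expect_equal(casson_viscosity(g, rhn), rep(0.1 * rhn$eta, length(g)))
  expect_error(casson_viscosity(-1, rh), "non-negative")
})

test_that("viscosity increases with hematocrit at fixed shear", {
  g <- 10^seq(-2, 4, length.out = 100)
  mu35 <- casson_viscosity(g, rheology_params(H = 0.35))
  mu45 <- casson_viscosity(g, rheology_params(H = 0.45))
  expect_true(all(mu45 > mu35))
})

test_that("shear-rate magnitude is the second invariant of the strain rate", {
  expect_equal(shear_rate_magnitude(0, 3, 0, 0), 3)   # simple shear
  expect_equal(shear_rate_magnitude(0, -3, 0, 0), 3)
  expect_equal(shear_rate_magnitude(0, 1, -1, 0), 0)  # rigid rotation
  expect_equal(shear_rate_magnitude(2, 0, 0, -2), 4)  # pure extension
  # frame invariance under rotation of coordinates
  set.seed(7)
  for (k in 1:20) {
    G <- matrix(rnorm(4), 2, 2)
    th <- runif(1, 0, 2 * pi)
    Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Gr <- Q %*% G %*% t(Q)
    expect_equal(shear_rate_magnitude(G[1, 1], G[1, 2], G[2, 1], G[2, 2]),
                 shear_rate_magnitude(Gr[1, 1], Gr[1, 2], Gr[2, 1], Gr[2, 2]),
                 tolerance = 1e-12)
  }
})
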