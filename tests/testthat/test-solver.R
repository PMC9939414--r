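test_that("Kozeny-Carman permeability matches direct evaluation and scaling", {
  expect_equal(permeability(0.89, 2.5e-4),
               (2.5e-4)^2 * 0.89^3 / (180 * 0.11^2), tolerance = 1e-15)
  expect_equal(permeability(0.89, 2.5e-4), 2.02e-8, tolerance = 0.01)
  expect_equal(permeability(0.79, 2.5e-4), 3.88e-9, tolerance = 0.01)
  phi <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(permeability(phi)) > 0))
  expect_equal(permeability(0.6, 5e-4) / permeability(0.6, 2.5e-4), 4)
  expect_error(permeability(0), "porosity")
  expect_error(permeability(1), "porosity")
  expect_lt(coil_model(0.79)$K, coil_model(0.89)$K)
})

test_that("momentum sink applies Darcy drag in coil and penalization in wall", {
  geom <- set_coil(build_geometry(geometry_params()), 1)
  coil <- coil_model(0.89)
  zero <- uniform_snapshot(geom, 0, 0)
  s0 <- momentum_sink(zero, geom, coil)
  expect_true(all(s0$fx == 0) && all(s0$fy == 0))
  snap <- uniform_snapshot(geom, 0.1, 0)
  s1 <- momentum_sink(snap, geom, coil, eps = 1e-5, rho = 1060)
  ic <- which(geom$coil_mask)[1]
  expect_equal(abs(s1$fx[ic]), snap$mu[ic] * 0.1 / coil$K)
  iw <- which(!geom$lumen_mask)[1]
  expect_equal(abs(s1$fx[iw]), 1060 / 1e-5 * 0.1)
  ifree <- which(geom$lumen_mask & !geom$coil_mask)[1]
  expect_equal(s1$fx[ifree], 0)
})

test_that("direct Poisson solver agrees with a dense reference solve", {
  nx <- 8L; ny <- 6L; dx <- 0.1
  basis <- coilflow:::poisson_basis(ny, dx)
  set.seed(3)
  rhs <- matrix(rnorm(nx * ny), nx, ny)
  p <- coilflow:::poisson_solve_cpp(rhs, basis$V, basis$lam, dx)
  # dense 5-point Laplacian: mirror ghosts left/top/bottom (Neumann),
  # antisymmetric ghost at the outlet column (Dirichlet at the face)
  idx <- function(i, j) (j - 1) * nx + i
  A <- matrix(0, nx * ny, nx * ny)
  for (j in 1:ny) for (i in 1:nx) {
    k <- idx(i, j); diag_c <- -4
    if (i > 1) A[k, idx(i - 1, j)] <- 1 else diag_c <- diag_c + 1
    if (i < nx) A[k, idx(i + 1, j)] <- 1 else diag_c <- diag_c - 1
    if (j > 1) A[k, idx(i, j - 1)] <- 1 else diag_c <- diag_c + 1
    if (j < ny) A[k, idx(i, j + 1)] <- 1 else diag_c <- diag_c + 1
    A[k, k] <- diag_c
  }
  p_ref <- matrix(solve(A / dx^2, as.vector(rhs)), nx, ny)
  expect_equal(p, p_ref, tolerance = 1e-10)
})

test_that("zero inflow from rest is an exact fixed point", {
  geom <- build_geometry(geometry_params(grid_nx = 96, grid_ny = 56))
  st <- run_steady(geom, 0, rheology_params(H = 0.45), t_end = 0.02)
  expect_true(all(st$u == 0) && all(st$v == 0) && all(st$p == 0))
  expect_true(all(st$snapshot$uc == 0))
})

test_that("yield-free hematocrit equals the explicit newtonian switch", {
  geom <- build_geometry(geometry_params(grid_nx = 96, grid_ny = 56))
  a <- run_steady(geom, 0.2, rheology_params(H = 0), t_end = 0.05)
  b <- run_steady(geom, 0.2, rheology_params(H = 0.45, newtonian = TRUE),
                  t_end = 0.05)
  expect_lt(max(abs(a$u - b$u)), 1e-10)
  expect_lt(max(abs(a$p - b$p)), 1e-10)
})

test_that("divergence, mass balance and solid slip meet their contracts", {
  b <- poiseuille_bench()
  s <- b$series
  u_peak <- 1.5 * 0.25
  geom_dx <- 4e-3 / 64
  expect_lt(max(s$max_div), 1e-6 * u_peak / geom_dx)
  late <- s$t > 0.1
  expect_lt(max(abs(s$q_in[late] - s$q_out[late]) / abs(s$q_in[late])), 0.005)
  expect_lt(s$max_u_solid[nrow(s)], 1e-3 * u_peak)
})

test_that("halving the penalization time at least halves residual slip", {
  geom <- build_geometry(geometry_params(grid_nx = 96, grid_ny = 56))
  slip <- vapply(c(4e-5, 2e-5), function(eps) {
    cfg <- solver_config(penalization_time = eps)
    st <- run_steady(geom, 0.3, rheology_params(H = 0), config = cfg,
                     t_end = 0.15)
    st$series$max_u_solid[nrow(st$series)]
  }, numeric(1))
  expect_lt(slip[2], 0.55 * slip[1])
})

test_that("solver configuration enforces the protocol invariants", {
  expect_error(solver_config(cycles = 2), "cycles")
  expect_error(solver_config(cfl = 0.8), "cfl")
  expect_error(solver_config(poisson_rel_tol = 1e-6), "poisson")
  expect_error(solver_config(snapshots_per_cycle = 8), "snapshots")
  geom <- build_geometry(geometry_params())
  expect_error(run_cycles(geom, synth_waveform(), rheology_params(),
                          coil = coil_model(0.89)),
               "coil mask")
})
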