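#' Coil model: porosity, wire diameter and Kozeny-Carman permeability
#'
#' The endovascular coil mass is modelled as an isotropic porous medium.
#' Its permeability follows the Kozeny-Carman granular closure with the
#' coil wire diameter as the grain diameter:
#' \deqn{K = \frac{d_w^2\,\varphi^3}{180\,(1-\varphi)^2}.}
#' K is strictly increasing in the porosity \eqn{\varphi}, so the lower
#' porosity packing (0.79) is the less permeable, more flow-damping one.
#'
#' @param porosity Coil-mass void fraction \eqn{\varphi}, strictly inside
#'   (0, 1). The study values are 0.89 and 0.79.
#' @param wire_diameter Coil wire diameter \eqn{d_w}, m (default 0.25 mm,
#'   a typical platinum coil).
#' @return An object of class \code{"coil_model"} with fields
#'   \code{porosity}, \code{wire_diameter}, \code{K} (m^2).
#' @export
#' @examples
#' coil_model(0.89)$K   # ~2.0e-8 m^2
#' coil_model(0.79)$K   # ~3.9e-9 m^2
coil_model <- function(porosity, wire_diameter = 2.5e-4) {
  structure(list(porosity = porosity, wire_diameter = wire_diameter,
                 K = permeability(porosity, wire_diameter)),
            class = "coil_model")
}

#' Kozeny-Carman permeability of the coil packing
#'
#' @inheritParams coil_model
#' @return Permeability K, m^2.
#' @export
permeability <- function(porosity, wire_diameter = 2.5e-4) {
  if (!is.numeric(porosity) || any(!is.finite(porosity)) ||
      any(porosity <= 0) || any(porosity >= 1))
    stop("porosity must lie strictly inside (0, 1)")
  if (!is.numeric(wire_diameter) || any(wire_diameter <= 0))
    stop("wire_diameter must be positive")
  wire_diameter^2 * porosity^3 / (180 * (1 - porosity)^2)
}

#' @export
print.coil_model <- function(x, ...) {
  cat(sprintf("Coil model: porosity %.2f, wire %.3g mm, K = %.3g m^2\n",
              x$porosity, 1e3 * x$wire_diameter, x$K))
  invisible(x)
}

#' Solver configuration
#'
#' @param cfl Advective CFL number in (0, 0.5]; sets the time step as
#'   \code{cfl * dx / u_max} with \code{u_max} the expected peak velocity.
#'   Diffusion and the sink terms are point-implicit, so no viscous or
#'   Darcy stability limit applies.
#' @param poisson_rel_tol Pressure-solve tolerance contract. The pressure
#'   Poisson equation is solved by a direct fast solver (cosine
#'   eigen-transform + tridiagonal sweeps), whose residual is at rounding
#'   level and in particular always below this bound.
#' @param penalization_time Brinkman penalization time constant
#'   \eqn{\epsilon}, s. Residual slip inside the wall scales linearly with
#'   it.
#' @param cycles Number of cardiac cycles integrated from rest; at least
#'   3, so that the final analysed cycle is free of start-up transients.
#' @param snapshots_per_cycle Uniformly spaced field snapshots recorded
#'   per cycle (>= 16; the wall-series quadratures need them).
#' @param ramp_fraction Fraction of the first cycle over which the inflow
#'   is ramped from zero (avoids an impulsive start).
#' @return An object of class \code{"solver_config"}.
#' @export
solver_config <- function(cfl = 0.4, poisson_rel_tol = 1e-10,
                          penalization_time = 1e-5, cycles = 3,
                          snapshots_per_cycle = 32, ramp_fraction = 0.05) {
  stopifnot(cfl > 0, cfl <= 0.5, poisson_rel_tol <= 1e-8,
            penalization_time > 0, snapshots_per_cycle >= 16,
            ramp_fraction >= 0, ramp_fraction < 1)
  cycles <- as.integer(cycles)
  if (cycles < 3)
    stop("cycles must be >= 3: the analysis protocol discards the first ",
         "two cycles as start-up transient")
  structure(list(cfl = cfl, poisson_rel_tol = poisson_rel_tol,
                 penalization_time = penalization_time, cycles = cycles,
                 snapshots_per_cycle = as.integer(snapshots_per_cycle),
                 ramp_fraction = ramp_fraction),
            class = "solver_config")
}

# ---- internal solver plumbing ---------------------------------------------

# Solid fraction on u- and v-faces from the cell-centered level function:
# a one-cell smoothed Heaviside of the face-interpolated sdf. Gives the
# penalization sub-cell wall accuracy.
face_solid_fractions <- function(geometry) {
  sdf <- geometry$sdf; nx <- geometry$nx; ny <- geometry$ny; dx <- geometry$dx
  sdf_u <- matrix(0, nx + 1, ny)
  sdf_u[2:nx, ] <- 0.5 * (sdf[1:(nx - 1), ] + sdf[2:nx, ])
  sdf_u[1, ] <- sdf[1, ]; sdf_u[nx + 1, ] <- sdf[nx, ]
  sdf_v <- matrix(0, nx, ny + 1)
  sdf_v[, 2:ny] <- 0.5 * (sdf[, 1:(ny - 1)] + sdf[, 2:ny])
  sdf_v[, 1] <- sdf[, 1]; sdf_v[, ny + 1] <- sdf[, ny]
  # sharp masks: a face is penalized iff its center lies in the solid;
  # sub-cell wall position is recovered by the one-sided viscous stencils
  list(chi_u = (sdf_u >= 0) * 1.0, chi_v = (sdf_v >= 0) * 1.0,
       sdf_u = sdf_u, sdf_v = sdf_v)
}

face_coil_fractions <- function(geometry) {
  cm <- geometry$coil_mask * 1.0; nx <- geometry$nx; ny <- geometry$ny
  cu <- matrix(0, nx + 1, ny)
  cu[2:nx, ] <- 0.5 * (cm[1:(nx - 1), ] + cm[2:nx, ])
  cu[1, ] <- cm[1, ]; cu[nx + 1, ] <- cm[nx, ]
  cv <- matrix(0, nx, ny + 1)
  cv[, 2:ny] <- 0.5 * (cm[, 1:(ny - 1)] + cm[, 2:ny])
  cv[, 1] <- cm[, 1]; cv[, ny + 1] <- cm[, ny]
  list(chic_u = cu, chic_v = cv)
}

# Orthonormal cosine (DCT-II) eigenbasis of the 1D cell-centered Neumann
# Laplacian across y, and its eigenvalues, for the direct Poisson solver.
poisson_basis <- function(ny, dx) {
  j <- seq_len(ny) - 0.5
  V <- sapply(seq_len(ny) - 1L, function(k) cos(k * pi * j / ny))
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  lam <- (2 * cos((seq_len(ny) - 1L) * pi / ny) - 2) / dx^2
  list(V = V, lam = lam)
}

# Parabolic inlet profile on cell centers, unit mean over the open gap.
parabolic_inlet <- function(geometry) {
  yc <- cell_centers_y(geometry$ny, geometry$dx)
  ymid <- 0.5 * (geometry$y_bot + geometry$y_top)
  h2 <- (geometry$y_top - geometry$y_bot) / 2
  prof <- 1.5 * pmax(0, 1 - ((yc - ymid) / h2)^2)
  prof
}

# Assemble the setup list and call the compiled kernel.
run_solver <- function(geometry, inlet_prof, inlet_t0, inlet_dt,
                       rheology, coil = NULL, config = solver_config(),
                       dt, t_end, rec_times, series_every = 25L) {
  chi <- face_solid_fractions(geometry)
  chic <- face_coil_fractions(geometry)
  basis <- poisson_basis(geometry$ny, geometry$dx)
  tau_y <- if (rheology$newtonian) 0 else rheology$tau_y
  setup <- list(nx = geometry$nx, ny = geometry$ny, dx = geometry$dx,
                dt = dt, t_end = t_end, rho = rheology$rho,
                eta = rheology$eta, tau_y = tau_y, m = rheology$m,
                eps = config$penalization_time,
                K = if (is.null(coil)) -1 else coil$K,
                chi_u = chi$chi_u, chi_v = chi$chi_v,
                sdf_u = chi$sdf_u, sdf_v = chi$sdf_v,
                chic_u = chic$chic_u, chic_v = chic$chic_v,
                lumen = geometry$lumen_mask * 1L,
                sac = geometry$sac_mask * 1L,
                deep_solid = (geometry$sdf >= geometry$dx) * 1L,
                inlet_prof = inlet_prof, inlet_t0 = inlet_t0,
                inlet_dt = inlet_dt,
                V = basis$V, lam = basis$lam,
                rec_times = sort(rec_times),
                series_every = as.integer(series_every))
  run_flow_cpp(setup)
}

time_step <- function(geometry, config, u_max) {
  # 1.5 u_max: peak of the parabolic profile at the largest inlet mean;
  # interior velocities stay below it (verified on the study conditions)
  config$cfl * geometry$dx / max(1.5 * u_max, 0.05)
}

snapshot_from_raw <- function(raw, k, geometry) {
  structure(list(uc = raw$uc[, , k], vc = raw$vc[, , k],
                 p = raw$p[, , k], mu = raw$mu[, , k],
                 t = raw$rec_t[k], dx = geometry$dx),
            class = "flow_snapshot")
}

#' Darcy / penalization momentum sink field
#'
#' Evaluates the volumetric momentum sink on cell centers: inside the coil
#' region \eqn{-(\mu/K)\,\mathbf u} (Darcy drag), inside the solid wall
#' \eqn{-(\rho/\epsilon)\,\mathbf u} (Brinkman penalization), zero
#' elsewhere. The time integrator applies exactly these coefficients,
#' pointwise implicitly.
#'
#' @param state A \code{flow_snapshot} (cell-centered \code{uc}, \code{vc},
#'   \code{mu}) or a list with those fields.
#' @param geometry An [build_geometry()] result (with coil mask set for
#'   coiled runs).
#' @param coil A [coil_model()], or NULL for an uncoiled run.
#' @param eps Penalization time constant, s.
#' @param rho Density, kg/m^3.
#' @return List of force-density fields \code{fx}, \code{fy} (N/m^3).
#' @export
momentum_sink <- function(state, geometry, coil = NULL, eps = 1e-5,
                          rho = 1060) {
  solid <- !geometry$lumen_mask
  fx <- matrix(0, geometry$nx, geometry$ny)
  fy <- matrix(0, geometry$nx, geometry$ny)
  fx[solid] <- -rho / eps * state$uc[solid]
  fy[solid] <- -rho / eps * state$vc[solid]
  if (!is.null(coil)) {
    cm <- geometry$coil_mask & !solid
    fx[cm] <- -state$mu[cm] / coil$K * state$uc[cm]
    fy[cm] <- -state$mu[cm] / coil$K * state$vc[cm]
  }
  list(fx = fx, fy = fy)
}

#' Integrate the pulsatile cycles and collect wall series and snapshots
#'
#' Runs the projection solver from rest through \code{config$cycles}
#' cardiac cycles of the given inlet waveform (ramped over the first few
#' percent of cycle 1), recording uniformly spaced field snapshots in
#' every cycle plus the four cardiac phase instants of every cycle.
#' Signed wall shear stress and wall pressure are sampled along the wall
#' chain at every recorded instant; the four phase snapshots of the final
#' cycle are returned as full fields.
#'
#' @param geometry An [build_geometry()] result (call [set_coil()] first
#'   for coiled runs).
#' @param waveform An [synth_waveform()] object.
#' @param rheology An [rheology_params()] object.
#' @param coil A [coil_model()] or NULL (uncoiled). A coil model with an
#'   empty coil mask is rejected.
#' @param config A [solver_config()].
#' @return An object of class \code{"flow_run"}: list with
#'   \code{wall_series} (final-cycle \code{s}, \code{t}, matrices
#'   \code{tau_w} and \code{p_w} of size n_wall x n_t, validity mask),
#'   \code{phase_snapshots} (named list of four \code{flow_snapshot}s),
#'   \code{phase_times}, \code{cycle_peak_wss} (per-cycle max in-view
#'   |WSS| at peak systole), \code{series} (flux / divergence / sac
#'   kinetic-energy time series), \code{ke_sac_mean} (final-cycle mean),
#'   the inputs, and \code{dt}.
#' @export
run_cycles <- function(geometry, waveform, rheology, coil = NULL,
                       config = solver_config()) {
  stopifnot(inherits(geometry, "aneurysm_geometry"),
            inherits(waveform, "inlet_waveform"),
            inherits(rheology, "rheology_params"),
            inherits(config, "solver_config"))
  if (!is.null(coil)) {
    stopifnot(inherits(coil, "coil_model"))
    if (!any(geometry$coil_mask))
      stop("coil model supplied but geometry has an empty coil mask; ",
           "call set_coil() first")
  }
  Tp <- waveform$period
  ncyc <- config$cycles
  t_end <- ncyc * Tp
  dt <- time_step(geometry, config, waveform$u_peak)

  # inlet: parabolic profile scaled by the instantaneous waveform mean,
  # ramped over the first ramp_fraction of cycle 1
  prof <- parabolic_inlet(geometry)
  in_dt <- Tp / 1024
  in_t <- seq(0, t_end + 2 * in_dt, by = in_dt)
  ramp <- pmin(1, in_t / (config$ramp_fraction * Tp + 1e-300))
  inlet_prof <- outer(prof, waveform$u_fun(in_t) * ramp)

  # recording times: uniform per cycle + the four phase instants per cycle
  spc <- config$snapshots_per_cycle
  uni <- as.vector(outer(seq_len(spc) / spc * Tp, (seq_len(ncyc) - 1) * Tp, "+"))
  ph_rel <- waveform$phases %% Tp
  ph_all <- as.vector(outer(ph_rel, (seq_len(ncyc) - 1) * Tp, "+"))
  rec_times <- sort(unique(round(c(uni, ph_all), 12)))

  raw <- run_solver(geometry, inlet_prof, 0, in_dt, rheology, coil, config,
                    dt = dt, t_end = t_end, rec_times = rec_times)
  if (raw$n_recorded < length(rec_times))
    warning("solver recorded fewer snapshots than scheduled")
  rec_t <- raw$rec_t

  match_rec <- function(target) {
    vapply(target, function(tt) which.min(abs(rec_t - tt)), integer(1))
  }
  phase_names <- c("max_accel", "peak_sys", "max_decel", "early_dia")

  # final-cycle wall series (uniform samples of the last cycle)
  t0 <- (ncyc - 1) * Tp
  fin_idx <- match_rec(t0 + seq_len(spc) / spc * Tp)
  wall <- geometry$wall
  nT <- length(fin_idx)
  tau_w <- matrix(NA_real_, nrow(wall), nT)
  p_w <- matrix(NA_real_, nrow(wall), nT)
  valid <- matrix(FALSE, nrow(wall), nT)
  for (k in seq_len(nT)) {
    snap <- snapshot_from_raw(raw, fin_idx[k], geometry)
    ws <- wall_shear_stress(snap, geometry, rheology)
    tau_w[, k] <- ws$tau_w
    valid[, k] <- ws$valid
    p_w[, k] <- interp_bilinear(snap$p,
                                wall$x + 1.0 * geometry$dx * wall$nx,
                                wall$y + 1.0 * geometry$dx * wall$ny,
                                geometry$dx)
  }
  wall_series <- structure(list(s = wall$s, t = rec_t[fin_idx] - t0,
                                period = Tp, tau_w = tau_w, p_w = p_w,
                                valid = valid, in_view = wall$in_view),
                           class = "wall_series")

  # per-cycle peak-systolic max in-view WSS (cycle-periodicity check)
  cyc_peak <- numeric(ncyc)
  for (cc in seq_len(ncyc)) {
    k <- match_rec((cc - 1) * Tp + ph_rel["t_peak_sys"])
    ws <- wall_shear_stress(snapshot_from_raw(raw, k, geometry),
                            geometry, rheology)
    ok <- ws$valid & wall$in_view
    cyc_peak[cc] <- max(abs(ws$tau_w[ok]))
  }

  ph_idx <- match_rec(t0 + ph_rel)
  phase_snapshots <- stats::setNames(
    lapply(ph_idx, snapshot_from_raw, raw = raw, geometry = geometry),
    phase_names)

  ser <- raw$series
  ke_mean <- mean(ser$ke_sac[ser$t > t0])

  structure(list(wall_series = wall_series,
                 phase_snapshots = phase_snapshots,
                 phase_times = stats::setNames(rec_t[ph_idx] - t0, phase_names),
                 cycle_peak_wss = cyc_peak,
                 series = ser, ke_sac_mean = ke_mean,
                 geometry = geometry, waveform = waveform,
                 rheology = rheology, coil = coil, config = config,
                 dt = raw$dt, t_final = raw$t_final),
            class = "flow_run")
}

#' @export
print.flow_run <- function(x, ...) {
  cat("Pulsatile flow run\n")
  cat(sprintf("  %d cycles of %.3g s, dt = %.3g s, grid %d x %d\n",
              x$config$cycles, x$waveform$period, x$dt,
              x$geometry$nx, x$geometry$ny))
  cat(sprintf("  rheology H = %.2f%s, coil: %s\n", x$rheology$H,
              if (x$rheology$newtonian) " (newtonian)" else "",
              if (is.null(x$coil)) "none"
              else sprintf("porosity %.2f", x$coil$porosity)))
  cat(sprintf("  per-cycle peak-systolic max WSS [Pa]: %s\n",
              paste(sprintf("%.4f", x$cycle_peak_wss), collapse = ", ")))
  cat(sprintf("  final-cycle mean sac kinetic energy: %.4g J/m\n", x$ke_sac_mean))
  invisible(x)
}

#' Steady-state solve at frozen inflow
#'
#' Integrates the solver with a constant inlet condition (short ramp from
#' rest) until \code{t_end} and returns the final snapshot. Used by the
#' grid-convergence harness and the analytic benchmarks.
#'
#' @param geometry,rheology,coil,config As in [run_cycles()].
#' @param u_in Inlet mean velocity, m/s (parabolic profile), ignored if
#'   \code{inlet_profile} is given.
#' @param t_end Integration time, s; choose a few advective
#'   flow-through times.
#' @param inlet_profile Optional function \code{f(y, t)} giving the inlet
#'   velocity on cell-center ordinates (overrides the parabolic profile;
#'   used by the Womersley and Casson-channel benchmarks).
#' @param u_scale Velocity scale for the CFL time step when
#'   \code{inlet_profile} is given.
#' @param ramp_time Inlet ramp duration, s.
#' @return List with \code{snapshot} (a \code{flow_snapshot}),
#'   \code{series}, \code{dt}, and the staggered final fields
#'   \code{u}, \code{v}.
#' @export
run_steady <- function(geometry, u_in, rheology, coil = NULL,
                       config = solver_config(), t_end = 0.4,
                       inlet_profile = NULL, u_scale = NULL,
                       ramp_time = 0.02) {
  stopifnot(inherits(geometry, "aneurysm_geometry"))
  in_dt <- max(t_end / 2048, 1e-4)
  in_t <- seq(0, t_end + 2 * in_dt, by = in_dt)
  ramp <- if (ramp_time > 0) pmin(1, in_t / ramp_time) else rep(1, length(in_t))
  if (is.null(inlet_profile)) {
    inlet_prof <- outer(parabolic_inlet(geometry), u_in * ramp)
    u_scale <- u_scale %||% u_in
  } else {
    yc <- cell_centers_y(geometry$ny, geometry$dx)
    inlet_prof <- sapply(in_t, function(tt) inlet_profile(yc, tt))
    inlet_prof <- sweep(inlet_prof, 2, ramp, "*")
    u_scale <- u_scale %||% max(abs(inlet_prof))
  }
  dt <- time_step(geometry, config, u_scale)
  raw <- run_solver(geometry, inlet_prof, 0, in_dt, rheology, coil, config,
                    dt = dt, t_end = t_end, rec_times = t_end,
                    series_every = 50L)
  list(snapshot = snapshot_from_raw(raw, 1L, geometry),
       series = raw$series, dt = raw$dt,
       u = raw$u_final, v = raw$v_final, p = raw$p_final)
}
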