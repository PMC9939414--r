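# Analytic validation benchmarks: each builds a plain-channel geometry,
# runs the solver in a regime with a closed-form solution, and reports
# relative errors against it.

channel_geometry <- function(n_gap = 64, length = 12e-3, width = 4e-3,
                             margin_cells = 4) {
  dx <- width / n_gap
  ny <- as.integer(n_gap + 2 * margin_cells)
  nx <- as.integer(round(length / dx))
  geometry_params(channel_width = width, channel_length = nx * dx,
                  neck_width = width * 0.75, dome1_radius = 0,
                  dome2_radius = 0, dome_offset = 0,
                  grid_nx = nx, grid_ny = ny, dx = dx,
                  wall_margin = margin_cells * dx)
}

#' Plane-Poiseuille benchmark
#'
#' Steady Newtonian channel flow at prescribed mean velocity: the
#' converged centerline velocity must match \eqn{1.5\,\bar u} and the
#' wall shear stress (extracted by the normal-probe scheme) must match
#' \eqn{6 \mu \bar u / h}.
#'
#' @param n_gap Cells across the channel gap.
#' @param u_mean Inlet mean velocity, m/s.
#' @param t_end Settling time, s.
#' @return A \code{benchmark_result} with the relative errors
#'   \code{err_centerline} and \code{err_wss}.
#' @export
benchmark_poiseuille <- function(n_gap = 64, u_mean = 0.25, t_end = 0.25) {
  geom <- build_geometry(channel_geometry(n_gap))
  rh <- rheology_params(H = 0, newtonian = TRUE)
  st <- run_steady(geom, u_mean, rh, t_end = t_end)
  mu <- 0.1 * rh$eta
  h <- geom$y_top - geom$y_bot
  ymid <- 0.5 * (geom$y_top + geom$y_bot)
  xprobe <- 0.7 * geom$Lx
  u_c <- interp_bilinear(st$snapshot$uc, xprobe, ymid, geom$dx)
  err_center <- abs(u_c - 1.5 * u_mean) / (1.5 * u_mean)
  ws <- wall_shear_stress(st$snapshot, geom, rh)
  wall <- geom$wall
  sel <- ws$valid & abs(wall$y - geom$y_bot) < geom$dx &
    wall$x > 0.4 * geom$Lx & wall$x < 0.85 * geom$Lx
  tau_ref <- 6 * mu * u_mean / h
  err_wss <- abs(mean(abs(ws$tau_w[sel])) - tau_ref) / tau_ref
  structure(list(name = "poiseuille",
                 err_centerline = err_center, err_wss = err_wss,
                 tol = c(err_centerline = 0.02, err_wss = 0.03),
                 u_centerline = u_c, tau_wall = mean(abs(ws$tau_w[sel])),
                 tau_ref = tau_ref, series = st$series),
            class = "benchmark_result")
}

#' Analytic oscillatory plane-channel (Womersley-type) profile
#'
#' The unidirectional oscillatory solution of the incompressible
#' Navier-Stokes equations in a plane channel of gap \code{h} driven at
#' angular frequency \code{omega}:
#' \deqn{u(y, t) = \Re\left\{\hat u\left(1 -
#'   \frac{\cosh(\sqrt{i\omega/\nu}\, y)}{\cosh(\sqrt{i\omega/\nu}\, h/2)}
#'   \right) e^{i\omega t}\right\},}
#' with \eqn{y} measured from the centerline. \code{u_amp} scales the
#' centerline amplitude to the requested value. The Womersley number is
#' \eqn{\alpha = (h/2)\sqrt{\omega/\nu}}.
#'
#' @param y Ordinates from the centerline, m.
#' @param t Time, s (scalar).
#' @param h Gap, m.
#' @param omega Angular frequency, rad/s.
#' @param nu Kinematic viscosity, m^2/s.
#' @param u_amp Centerline velocity amplitude, m/s.
#' @return Velocity samples, m/s (same length as \code{y}).
#' @export
womersley_profile <- function(y, t, h, omega, nu, u_amp = 0.1) {
  k <- sqrt(1i * omega / nu)
  shape <- 1 - cosh(k * y) / cosh(k * h / 2)
  shape0 <- 1 - 1 / cosh(k * h / 2)
  Re(u_amp * shape / abs(shape0) * exp(1i * omega * t))
}

#' Oscillatory channel-flow benchmark at Womersley number ~ 3
#'
#' Superimposes the analytic oscillatory profile (centerline amplitude
#' \code{u_osc}) on a steady Poiseuille base flow at the inlet and checks
#' that the solver transports the exact unsteady solution down the
#' channel: the fundamental-frequency amplitude of the centerline
#' velocity, extracted by Fourier projection over the final cycle,
#' must match \code{u_osc}.
#'
#' @param n_gap Cells across the gap.
#' @param period Oscillation period, s (0.8 s with the default blood
#'   parameters gives \eqn{\alpha \approx 3.1}).
#' @param u_base Mean of the steady base flow, m/s.
#' @param u_osc Centerline amplitude of the oscillatory part, m/s.
#' @param cycles Cycles integrated (the last one is analysed).
#' @return A \code{benchmark_result} with \code{err_amplitude} and the
#'   Womersley number \code{alpha}.
#' @export
benchmark_womersley <- function(n_gap = 40, period = 0.8, u_base = 0.2,
                                u_osc = 0.1, cycles = 3) {
  geom <- build_geometry(channel_geometry(n_gap))
  rh <- rheology_params(H = 0, newtonian = TRUE)
  mu <- 0.1 * rh$eta; nu <- mu / rh$rho
  h <- geom$y_top - geom$y_bot
  ymid <- 0.5 * (geom$y_top + geom$y_bot)
  omega <- 2 * pi / period
  alpha <- (h / 2) * sqrt(omega / nu)
  half <- h / 2
  inlet <- function(y, t) {
    inside <- y > geom$y_bot & y < geom$y_top
    yc <- y - ymid
    base <- 1.5 * u_base * pmax(0, 1 - (yc / half)^2)
    osc <- womersley_profile(pmin(pmax(yc, -half), half), t, h, omega, nu,
                             u_amp = u_osc)
    ifelse(inside, base + osc, 0)
  }
  t_end <- cycles * period
  # uniform snapshots over the final cycle for the Fourier projection
  nrec <- 64
  rec <- (cycles - 1) * period + seq_len(nrec) / nrec * period
  in_dt <- period / 2048
  in_t <- seq(0, t_end + 2 * in_dt, by = in_dt)
  yc <- cell_centers_y(geom$ny, geom$dx)
  ramp <- pmin(1, in_t / (0.1 * period))
  prof <- sapply(in_t, function(tt) inlet(yc, tt))
  prof <- sweep(prof, 2, ramp, "*")
  dt <- time_step(geom, solver_config(), (1.5 * u_base + u_osc) / 1.5)
  raw <- run_solver(geom, prof, 0, in_dt, rh, coil = NULL,
                    config = solver_config(), dt = dt, t_end = t_end,
                    rec_times = rec)
  xprobe <- 0.6 * geom$Lx
  uts <- vapply(seq_len(nrec), function(k)
    interp_bilinear(raw$uc[, , k], xprobe, ymid, geom$dx), numeric(1))
  tt <- raw$rec_t[seq_len(nrec)]
  amp <- 2 * abs(mean(uts * exp(-1i * omega * tt)))
  err <- abs(amp - u_osc) / u_osc
  structure(list(name = "womersley", alpha = alpha,
                 err_amplitude = err, tol = c(err_amplitude = 0.05),
                 amplitude = amp, amplitude_ref = u_osc),
            class = "benchmark_result")
}

#' Darcy-limit porous-channel benchmark
#'
#' A slab of coil spanning the full channel cross-section, low
#' permeability (Darcy regime): at steady state the bulk velocity must
#' satisfy Darcy's law \eqn{\bar u = (K/\mu)\,|dp/dx|} against the
#' measured pressure gradient inside the slab.
#'
#' @param n_gap Cells across the gap.
#' @param porosity Coil porosity of the slab.
#' @param u_in Prescribed inlet mean velocity, m/s.
#' @param t_end Settling time, s.
#' @return A \code{benchmark_result} with \code{err_darcy}.
#' @export
benchmark_darcy <- function(n_gap = 40, porosity = 0.5, u_in = 0.02,
                            t_end = 0.6) {
  geom <- build_geometry(channel_geometry(n_gap))
  # coil slab across the full lumen in the middle third of the channel
  xc <- cell_centers_x(geom$nx, geom$dx)
  slab <- matrix(xc >= geom$Lx / 3 & xc <= 2 * geom$Lx / 3,
                 geom$nx, geom$ny) & geom$lumen_mask
  geom$coil_mask <- slab
  coil <- coil_model(porosity)
  rh <- rheology_params(H = 0, newtonian = TRUE)
  mu <- 0.1 * rh$eta
  st <- run_steady(geom, u_in, rh, coil = coil, t_end = t_end,
                   u_scale = u_in)
  ymid <- 0.5 * (geom$y_top + geom$y_bot)
  xs <- seq(geom$Lx / 3 + 6 * geom$dx, 2 * geom$Lx / 3 - 6 * geom$dx,
            by = geom$dx)
  ps <- interp_bilinear(st$snapshot$p, xs, rep(ymid, length(xs)), geom$dx)
  dpdx <- abs(stats::coef(stats::lm(ps ~ xs))[["xs"]])
  u_darcy <- coil$K / mu * dpdx
  # bulk velocity through the slab = prescribed mean (mass conservation)
  h <- geom$y_top - geom$y_bot
  yc <- cell_centers_y(geom$ny, geom$dx)
  mid_i <- round(geom$nx / 2)
  open <- yc > geom$y_bot & yc < geom$y_top
  u_bulk <- mean(st$snapshot$uc[mid_i, open])
  err <- abs(u_bulk - u_darcy) / u_darcy
  structure(list(name = "darcy", err_darcy = err,
                 tol = c(err_darcy = 0.05),
                 u_bulk = u_bulk, u_darcy = u_darcy, dpdx = dpdx,
                 K = coil$K), class = "benchmark_result")
}

# 1D steady regularized-Casson channel profile: tau(y) = G*y from the
# centerline; invert mu(g)*g = |tau| pointwise, integrate from the wall.
casson_channel_profile <- function(y, G, h, rheology, n_fine = 2001) {
  yy <- seq(0, h / 2, length.out = n_fine)
  gdot <- vapply(yy, function(yp) {
    tau <- G * yp
    if (tau <= 0) return(0)
    f <- function(g) casson_viscosity(g, rheology) * g - tau
    up <- max(tau / (0.1 * rheology$eta), 1)
    stats::uniroot(f, c(0, 2 * up), tol = 1e-14)$root
  }, numeric(1))
  # u(y) = int_y^{h/2} gdot dy'
  cum <- rev(cumsum(rev(c(diff(yy) * (gdot[-1] + gdot[-n_fine]) / 2, 0))))
  stats::approx(yy, cum, xout = pmin(abs(y), h / 2), rule = 2)$y
}

#' Casson channel-flow benchmark
#'
#' Steady non-Newtonian channel flow with the regularized Casson law:
#' the exact fully developed profile (computed by pointwise inversion of
#' the shear-stress relation and quadrature) is prescribed at the inlet
#' and must be transported unchanged down the channel.
#'
#' @param n_gap Cells across the gap.
#' @param H Hematocrit of the test fluid.
#' @param G Driving pressure gradient, Pa/m.
#' @param t_end Settling time, s.
#' @return A \code{benchmark_result} with \code{err_profile} (max
#'   relative deviation over the core where \eqn{u > 0.1 u_{max}}).
#' @export
benchmark_casson_channel <- function(n_gap = 48, H = 0.45, G = 600,
                                     t_end = 0.3) {
  geom <- build_geometry(channel_geometry(n_gap))
  rh <- rheology_params(H = H)
  h <- geom$y_top - geom$y_bot
  ymid <- 0.5 * (geom$y_top + geom$y_bot)
  # tabulate the 1D oracle once; the inlet closure and the downstream
  # comparison both interpolate it
  ytab <- seq(ymid, geom$y_top, length.out = 401)
  utab <- casson_channel_profile(ytab - ymid, G, h, rh)
  u_exact <- function(y) stats::approx(c(2 * ymid - rev(ytab[-1]), ytab),
                                       c(rev(utab[-1]), utab), xout = y,
                                       rule = 2)$y
  inlet <- function(y, t) ifelse(y > geom$y_bot & y < geom$y_top, u_exact(y), 0)
  u_max <- max(utab)
  st <- run_steady(geom, NA, rh, t_end = t_end, inlet_profile = inlet,
                   u_scale = u_max)
  xprobe <- 0.7 * geom$Lx
  yy <- seq(geom$y_bot + 2 * geom$dx, geom$y_top - 2 * geom$dx,
            length.out = 101)
  u_num <- interp_bilinear(st$snapshot$uc, rep(xprobe, length(yy)), yy, geom$dx)
  u_ref <- u_exact(yy)
  core <- u_ref > 0.1 * u_max
  err <- max(abs(u_num[core] - u_ref[core]) / u_max)
  structure(list(name = "casson_channel", err_profile = err,
                 tol = c(err_profile = 0.03),
                 u_max = u_max), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark %s\n", x$name))
  for (nm in names(x$tol)) {
    v <- x[[nm]]
    cat(sprintf("  %-16s %.4g  (tolerance %.3g)  %s\n", nm, v, x$tol[[nm]],
                if (v <= x$tol[[nm]]) "PASS" else "FAIL"))
  }
  invisible(x)
}
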