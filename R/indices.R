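#' Signed wall shear stress along the wall chain
#'
#' For each wall point, tangential velocity is sampled at 1.5 dx and 3 dx
#' along the inward normal (bilinear interpolation of the cell-centered
#' velocity); the wall-normal derivative is the one-sided second-order
#' difference through the no-slip value u_t(0) = 0,
#' \eqn{\partial u_t/\partial n = (4 u_t(h) - u_t(2h)) / (2h)}, and
#' \eqn{\tau_w = \mu(\dot\gamma_w)\,\partial u_t/\partial n} with
#' \eqn{\dot\gamma_w = |\partial u_t/\partial n|}. The sign follows the
#' wall-chain orientation (positive along the tangent that keeps the lumen
#' on the left). Points whose probes leave the lumen (under-resolved
#' corners) are marked invalid.
#'
#' @param snapshot A \code{flow_snapshot} (fields \code{uc}, \code{vc},
#'   cell-centered) as returned inside [run_cycles()] / [run_steady()].
#' @param geometry The [build_geometry()] result the snapshot was
#'   computed on.
#' @param rheology The [rheology_params()] of the run (for the wall
#'   viscosity).
#' @return List with \code{s} (arc length), \code{tau_w} (signed, Pa;
#'   NA where invalid), \code{valid} (logical), \code{n_invalid}.
#' @export
wall_shear_stress <- function(snapshot, geometry, rheology) {
  wall <- geometry$wall
  dx <- geometry$dx
  h <- 1.5 * dx
  # tangent from the chain ordering (central difference along the closed
  # chain): the sign of tau_w follows the direction of travel
  n <- nrow(wall)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  txr <- wall$x[ip] - wall$x[im]; tyr <- wall$y[ip] - wall$y[im]
  tn <- sqrt(txr^2 + tyr^2)
  tx <- txr / tn; ty <- tyr / tn
  px1 <- wall$x + h * wall$nx; py1 <- wall$y + h * wall$ny
  px2 <- wall$x + 2 * h * wall$nx; py2 <- wall$y + 2 * h * wall$ny
  inside <- function(x, y) interp_bilinear(geometry$sdf, x, y, dx) < 0
  valid <- inside(px1, py1) & inside(px2, py2)
  ut1 <- interp_bilinear(snapshot$uc, px1, py1, dx) * tx +
    interp_bilinear(snapshot$vc, px1, py1, dx) * ty
  ut2 <- interp_bilinear(snapshot$uc, px2, py2, dx) * tx +
    interp_bilinear(snapshot$vc, px2, py2, dx) * ty
  dudn <- (4 * ut1 - ut2) / (2 * h)
  mu_w <- casson_viscosity(abs(dudn), rheology)
  tau <- mu_w * dudn
  tau[!valid] <- NA_real_
  list(s = wall$s, tau_w = tau, valid = valid, n_invalid = sum(!valid))
}

# periodic trapezoid weights for samples covering one period
periodic_weights <- function(t, period) {
  n <- length(t)
  tn <- c(t, t[1] + period)
  0.5 * (diff(tn) + c(tn[n + 1] - tn[n], diff(t)))
}

check_series <- function(series) {
  stopifnot(!is.null(series$t), !is.null(series$tau_w), !is.null(series$period))
  if (length(series$t) < 16)
    stop("wall series has fewer than 16 samples per cycle; ",
         "quadrature unreliable")
  if (max(series$t) - min(series$t) > series$period + 1e-9)
    stop("wall series spans more than one period")
  invisible(series)
}

#' Oscillatory shear index over the final cycle
#'
#' The standard oscillatory shear index of the signed wall shear,
#' \deqn{\mathrm{OSI}(s) = \tfrac12\left(1 -
#'   \frac{|\int \tau_w\,dt|}{\int |\tau_w|\,dt}\right),}
#' integrated over one period with periodic trapezoidal quadrature.
#' 0 where the shear never changes sign, 0.5 for zero-mean fully
#' oscillatory shear; points with identically zero shear get OSI = 0.
#'
#' @param series A \code{wall_series} (from [run_cycles()]) or any list
#'   with fields \code{t} (>= 16 sample instants covering one period),
#'   \code{period}, and \code{tau_w} (n_points x n_t matrix, or a vector
#'   for a single point).
#' @return OSI per wall point, in [0, 0.5]; NA where the series has
#'   invalid samples.
#' @export
osi <- function(series) {
  check_series(series)
  tau <- series$tau_w
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = 1)
  w <- periodic_weights(series$t, series$period)
  num <- abs(as.vector(tau %*% w))
  den <- as.vector(abs(tau) %*% w)
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(out, 0), 0.5)
}

#' Time-averaged wall shear stress magnitude over the final cycle
#'
#' \eqn{\mathrm{TAWSS}(s) = \frac1T \int |\tau_w(s, t)|\,dt}, periodic
#' trapezoidal quadrature; always at least the magnitude of the time-mean
#' signed shear, with equality where the sign never changes.
#'
#' @inheritParams osi
#' @return TAWSS per wall point, Pa.
#' @export
tawss <- function(series) {
  check_series(series)
  tau <- series$tau_w
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = 1)
  w <- periodic_weights(series$t, series$period)
  as.vector(abs(tau) %*% w) / series$period
}

# OSI accumulated from the cycle start up to time t_upto (open trapezoid;
# the per-instant OSI of the phase comparisons).
osi_running <- function(series, t_upto) {
  tau <- series$tau_w
  keep <- which(series$t <= t_upto + 1e-12)
  if (length(keep) < 2) return(rep(0, nrow(tau)))
  tk <- series$t[keep]
  w <- c(diff(tk) / 2, 0) + c(0, diff(tk) / 2)
  sub <- tau[, keep, drop = FALSE]
  num <- abs(as.vector(sub %*% w))
  den <- as.vector(abs(sub) %*% w)
  ifelse(den > 0, 0.5 * (1 - num / den), 0)
}

#' Average velocity magnitude across the neck plane
#'
#' Velocity magnitude averaged over sample points uniformly spaced along
#' the neck segment (bilinear interpolation), the sac-inflow metric of
#' the grid-convergence harness.
#'
#' @param snapshot A \code{flow_snapshot}.
#' @param geometry The matching geometry; must have a neck segment strictly
#'   inside the lumen.
#' @param n_samples Number of sample points (>= 32).
#' @return Mean velocity magnitude, m/s.
#' @export
neck_average_velocity <- function(snapshot, geometry, n_samples = 64) {
  stopifnot(n_samples >= 32)
  ns <- geometry$neck_segment
  f <- (seq_len(n_samples) - 0.5) / n_samples
  xs <- ns$x[1] + f * (ns$x[2] - ns$x[1])
  ys <- ns$y[1] + f * (ns$y[2] - ns$y[1])
  sd_mid <- interp_bilinear(geometry$sdf, mean(xs), mean(ys), geometry$dx)
  if (sd_mid >= 0)
    stop("neck segment does not lie inside the lumen")
  uu <- interp_bilinear(snapshot$uc, xs, ys, geometry$dx)
  vv <- interp_bilinear(snapshot$vc, xs, ys, geometry$dx)
  mean(sqrt(uu^2 + vv^2))
}

#' Per-phase hemodynamic index report for one run
#'
#' Collects the analysis quantities of a pulsatile run: TAWSS and OSI
#' along the wall over the final cycle, the per-phase maxima of |WSS| and
#' wall pressure over the in-view wall (sac plus parent wall within two
#' channel widths of the neck), per-phase running OSI maxima, per-phase
#' neck-plane average velocity, and the final-cycle mean sac kinetic
#' energy.
#'
#' @param run A [run_cycles()] result.
#' @param label Condition label stored in the report.
#' @return An object of class \code{"index_report"}.
#' @export
phase_metrics <- function(run, label = NULL) {
  stopifnot(inherits(run, "flow_run"))
  geometry <- run$geometry
  series <- run$wall_series
  wall_ok <- apply(series$valid, 1, all)
  view <- series$in_view & wall_ok
  frac_invalid <- 1 - mean(wall_ok[series$in_view])
  if (frac_invalid > 0.10)
    warning(sprintf(paste0("%.0f%% of in-view wall points have invalid WSS",
                           " probes; maxima may be unreliable"),
                    100 * frac_invalid))
  osi_s <- osi(series)
  tawss_s <- tawss(series)
  # OSI is degenerate where the shear magnitude sits at numerical noise
  # level (its sign is then arbitrary); OSI maxima are taken over wall
  # points carrying at least 0.5% of the run's peak TAWSS
  tau_floor <- 0.005 * max(tawss_s[view])
  view_osi <- view & tawss_s >= tau_floor

  phases <- names(run$phase_snapshots)
  max_wss <- max_p <- neck_v <- max_osi_ph <- stats::setNames(
    numeric(length(phases)), phases)
  for (ph in phases) {
    snap <- run$phase_snapshots[[ph]]
    ws <- wall_shear_stress(snap, geometry, run$rheology)
    ok <- ws$valid & series$in_view
    max_wss[ph] <- max(abs(ws$tau_w[ok]))
    pw <- interp_bilinear(snap$p,
                          geometry$wall$x + geometry$dx * geometry$wall$nx,
                          geometry$wall$y + geometry$dx * geometry$wall$ny,
                          geometry$dx)
    max_p[ph] <- max(pw[series$in_view])
    neck_v[ph] <- neck_average_velocity(snap, geometry)
    max_osi_ph[ph] <- max(osi_running(series, run$phase_times[[ph]])[view_osi])
  }

  structure(list(
    label = label %||% sprintf("H%.2f_%s", run$rheology$H,
                               if (is.null(run$coil)) "uncoiled"
                               else sprintf("phi%.2f", run$coil$porosity)),
    H = run$rheology$H,
    porosity = if (is.null(run$coil)) NA_real_ else run$coil$porosity,
    s = series$s, tawss = tawss_s, osi = osi_s, wall_valid = wall_ok,
    in_view = series$in_view,
    max_wss = max_wss, wall_pressure_max = max_p,
    neck_avg_velocity = neck_v, max_osi_phase = max_osi_ph,
    max_osi = max(osi_s[view_osi]),
    tau_floor = tau_floor,
    ke_sac_mean = run$ke_sac_mean,
    frac_invalid = frac_invalid,
    phase_times = run$phase_times,
    cycle_peak_wss = run$cycle_peak_wss,
    fingerprint = run$geometry$fingerprint,
    field_of_view = "sac wall + parent wall within 2 channel widths of neck",
    schema_version = "1.0"), class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf("Hemodynamic index report: %s\n", x$label))
  m <- rbind(`max WSS [Pa]` = x$max_wss,
             `max wall p [Pa]` = x$wall_pressure_max,
             `neck avg vel [m/s]` = x$neck_avg_velocity,
             `max OSI (running)` = x$max_osi_phase)
  print(round(m, 4))
  cat(sprintf("cycle max OSI %.4f | mean sac KE %.4g J/m | invalid wall %.1f%%\n",
              x$max_osi, x$ke_sac_mean, 100 * x$frac_invalid))
  invisible(x)
}

#' Export per-phase wall loads for one-way structural coupling
#'
#' Tabulates, for every wall point and each of the four phase instants,
#' the wall pressure load and the shear traction — the fluid-side input
#' of a one-way fluid-structure analysis of the aneurysm wall.
#'
#' @param run A [run_cycles()] result.
#' @param file Optional CSV output path.
#' @return A data frame with columns \code{s, x, y, phase, time, p_w,
#'   tau_w} (\code{n_wall_points * 4} rows), invisibly written to
#'   \code{file} if given.
#' @export
export_wall_loads <- function(run, file = NULL) {
  stopifnot(inherits(run, "flow_run"))
  geometry <- run$geometry
  wall <- geometry$wall
  out <- do.call(rbind, lapply(names(run$phase_snapshots), function(ph) {
    snap <- run$phase_snapshots[[ph]]
    ws <- wall_shear_stress(snap, geometry, run$rheology)
    pw <- interp_bilinear(snap$p, wall$x + geometry$dx * wall$nx,
                          wall$y + geometry$dx * wall$ny, geometry$dx)
    data.frame(s = wall$s, x = wall$x, y = wall$y, phase = ph,
               time = snap$t, p_w = pw, tau_w = ws$tau_w)
  }))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Percentage-change comparison across study conditions
#'
#' Tabulates, for every porosity contrast (phi 0.89 as reference vs 0.79)
#' at fixed hematocrit and every hematocrit contrast (H 0.45 as reference
#' vs 0.35) at fixed coiling, the per-phase percentage reduction
#' \eqn{100 (A - B)/A} (positive = reduction relative to the reference A)
#' and the absolute difference, for each reported metric.
#'
#' @param reports List of [phase_metrics()] reports computed on the same
#'   geometry and waveform (mismatched geometries are rejected).
#' @return An object of class \code{"comparison_report"}: a data frame
#'   with columns \code{contrast, metric, phase, ref, alt, ref_value,
#'   alt_value, reduction_pct, abs_diff}.
#' @export
compare_conditions <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 2,
            all(vapply(reports, inherits, logical(1), "index_report")))
  fp <- vapply(reports, `[[`, character(1), "fingerprint")
  if (length(unique(fp)) != 1)
    stop("reports computed on different geometries are not comparable")
  lab <- vapply(reports, `[[`, character(1), "label")
  names(reports) <- lab
  H <- vapply(reports, `[[`, numeric(1), "H")
  phi <- vapply(reports, `[[`, numeric(1), "porosity")
  metrics <- c("max_wss", "max_osi_phase", "wall_pressure_max",
               "neck_avg_velocity")
  pairs <- list()
  # porosity (coiling) contrasts at fixed hematocrit: chain from the
  # uncoiled baseline through descending porosity, the less-damped state
  # always the reference (uncoiled -> 0.89 -> 0.79)
  for (hh in unique(H)) {
    cc <- which(H == hh)
    if (length(cc) >= 2) {
      ord <- cc[order(ifelse(is.na(phi[cc]), 2, phi[cc]), decreasing = TRUE)]
      for (k in seq_len(length(ord) - 1))
        pairs[[length(pairs) + 1]] <- list(ref = ord[k], alt = ord[k + 1],
                                           contrast = "porosity")
    }
  }
  # hematocrit contrasts at fixed coil porosity: reference H = 0.45 -> 0.35
  for (ck in unique(phi[!is.na(phi)])) {
    cc <- which(!is.na(phi) & phi == ck)
    if (length(cc) >= 2) {
      ord <- cc[order(H[cc], decreasing = TRUE)]
      for (k in seq_len(length(ord) - 1))
        pairs[[length(pairs) + 1]] <- list(ref = ord[k], alt = ord[k + 1],
                                           contrast = "hematocrit")
    }
  }
  rows <- list()
  for (pr in pairs) {
    A <- reports[[pr$ref]]; B <- reports[[pr$alt]]
    for (mt in metrics) {
      av <- A[[mt]]; bv <- B[[mt]]
      rows[[length(rows) + 1]] <- data.frame(
        contrast = pr$contrast, metric = mt, phase = names(av),
        ref = A$label, alt = B$label,
        ref_value = unname(av), alt_value = unname(bv),
        reduction_pct = ifelse(av != 0, 100 * (av - bv) / av, NA_real_),
        abs_diff = unname(av - bv))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", class(out))
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Condition comparison (positive % = reduction vs reference)\n")
  y <- x
  y$ref_value <- signif(y$ref_value, 4)
  y$alt_value <- signif(y$alt_value, 4)
  y$reduction_pct <- round(y$reduction_pct, 2)
  y$abs_diff <- signif(y$abs_diff, 3)
  print.data.frame(y)
  invisible(x)
}
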