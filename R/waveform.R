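#' Synthesize a pulsatile inlet waveform with identifiable cardiac phases
#'
#' Builds a smooth, strictly positive, periodic inlet mean-velocity signal
#' with a single systolic peak, a dicrotic notch, and a diastolic decay —
#' the shape of a typical internal-carotid inflow trace. The signal is a
#' baseline plus two periodic von-Mises-type bumps (systolic pulse and a
#' smaller dicrotic wave), affinely mapped so its maximum is
#' \code{u_peak} and its minimum is \code{u_dia}.
#'
#' Four cardiac phase markers are detected from the signal:
#' \describe{
#'   \item{t_max_accel}{maximum of du/dt in the half-period before the peak}
#'   \item{t_peak_sys}{time of the systolic maximum}
#'   \item{t_max_decel}{minimum of du/dt in the half-period after the peak}
#'   \item{t_early_dia}{first local minimum of u after maximum deceleration
#'     (the dicrotic notch)}
#' }
#'
#' @param period Cardiac period, s.
#' @param u_dia Diastolic (minimum) inlet mean velocity, m/s.
#' @param u_peak Peak-systolic inlet mean velocity, m/s; must exceed
#'   \code{u_dia} (a constant signal has no definable phases).
#' @param systole_fraction Fraction of the cycle occupied by the systolic
#'   upstroke-plus-downstroke, in (0, 1).
#' @param n_samples Number of stored samples over one period (>= 64).
#'
#' @return An object of class \code{"inlet_waveform"}: list with
#'   \code{period}, \code{times} (in [0, period), length
#'   \code{n_samples}), \code{u_mean}, \code{phases} (named vector of the
#'   four marker times), \code{u_fun} (the analytic signal, vectorized,
#'   periodic), and \code{u_cycle_mean} (period mean of the analytic
#'   signal).
#' @export
#' @examples
#' wf <- synth_waveform()
#' wf$phases
synth_waveform <- function(period = 0.8, u_dia = 0.15, u_peak = 0.55,
                           systole_fraction = 0.35, n_samples = 256) {
  stopifnot(is.numeric(period), period > 0,
            is.numeric(u_dia), is.numeric(u_peak),
            is.numeric(systole_fraction), is.numeric(n_samples))
  if (!(u_dia > 0)) stop("u_dia must be positive (no inlet reversal)")
  if (!(u_peak > u_dia))
    stop("u_peak must exceed u_dia: a constant signal has undefined phases")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop("systole_fraction must lie in (0, 1)")
  n_samples <- as.integer(n_samples)
  if (n_samples < 64) stop("n_samples must be at least 64")

  # periodic bump exp(kappa (cos(2 pi (t - t0)/T) - 1)); widths tied to
  # the systolic fraction, dicrotic wave ~1/4 the pulse height
  sf <- systole_fraction
  t1 <- 0.45 * sf * period                 # systolic peak
  t2 <- sf * period + 0.18 * period        # dicrotic wave crest
  kappa1 <- 2 * log(2) / (pi * sf / 2)^2
  kappa2 <- 4 * kappa1
  bump <- function(t, t0, kappa) exp(kappa * (cos(2 * pi * (t - t0) / period) - 1))
  raw <- function(t) bump(t, t1, kappa1) + 0.25 * bump(t, t2, kappa2)

  tt_fine <- seq(0, period, length.out = 8193)[-8193]
  rv <- raw(tt_fine)
  r_min <- min(rv); r_max <- max(rv)
  u_fun <- function(t) u_dia + (u_peak - u_dia) * (raw(t) - r_min) / (r_max - r_min)

  times <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  u <- u_fun(times)
  uf <- u_fun(tt_fine)
  phases <- detect_phases(tt_fine, uf, period)
  structure(list(period = period, times = times, u_mean = u,
                 phases = phases, u_fun = u_fun,
                 u_cycle_mean = mean(uf),
                 u_dia = u_dia, u_peak = u_peak,
                 systole_fraction = systole_fraction,
                 n_samples = n_samples),
            class = "inlet_waveform")
}

#' Detect the four cardiac phase markers of a sampled periodic signal
#'
#' @param t Sample times covering exactly one period, uniformly spaced,
#'   without the duplicated endpoint.
#' @param u Signal samples at \code{t}; must not be constant.
#' @param period Signal period, s.
#' @return Named numeric vector \code{c(t_max_accel, t_peak_sys,
#'   t_max_decel, t_early_dia)}, strictly ordered within one period
#'   starting at \code{t_max_accel}.
#' @export
detect_phases <- function(t, u, period) {
  n <- length(t)
  stopifnot(length(u) == n, n >= 16)
  if (max(u) - min(u) <= 1e-12 * max(abs(u), 1))
    stop("constant signal: phase markers undefined")
  dt <- period / n
  # periodic central difference
  dudt <- (u[c(2:n, 1)] - u[c(n, 1:(n - 1))]) / (2 * dt)
  ip <- which.max(u)
  t_peak <- t[ip]
  half <- floor(n / 2)
  before <- ((ip - half):(ip - 1) - 1) %% n + 1
  after <- ((ip + 1):(ip + half) - 1) %% n + 1
  ia <- before[which.max(dudt[before])]
  id <- after[which.min(dudt[after])]
  # first local minimum strictly after maximum deceleration (cyclic scan)
  scan <- (id:(id + n - 2) - 1) %% n + 1
  ie <- NA_integer_
  for (k in scan) {
    km <- (k - 2) %% n + 1; kp <- k %% n + 1
    if (u[k] <= u[km] && u[k] < u[kp]) { ie <- k; break }
  }
  if (is.na(ie)) stop("no local minimum after maximum deceleration")
  unwrap <- function(tm, t0) t0 + (tm - t0) %% period
  ta <- t[ia]
  c(t_max_accel = ta,
    t_peak_sys = unwrap(t_peak, ta),
    t_max_decel = unwrap(t[id], ta),
    t_early_dia = unwrap(t[ie], ta))
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat("Pulsatile inlet waveform\n")
  cat(sprintf("  period %.3g s, u in [%.3g, %.3g] m/s, cycle mean %.3g m/s\n",
              x$period, x$u_dia, x$u_peak, x$u_cycle_mean))
  ph <- x$phases
  cat(sprintf("  phases [s]: max accel %.4f | peak sys %.4f | max decel %.4f | early dia %.4f\n",
              ph[1], ph[2] %% x$period, ph[3] %% x$period, ph[4] %% x$period))
  invisible(x)
}

#' @export
plot.inlet_waveform <- function(x, ...) {
  tt <- seq(0, x$period, length.out = 512)
  graphics::plot(tt, x$u_fun(tt), type = "l", lwd = 2,
                 xlab = "t [s]", ylab = "inlet mean velocity [m/s]",
                 main = "inlet waveform", ...)
  ph <- x$phases %% x$period
  graphics::abline(v = ph, lty = 3, col = "grey40")
  graphics::points(ph, x$u_fun(ph), pch = 19, col = "red3")
  graphics::text(ph, x$u_fun(ph),
                 c("max accel", "peak sys", "max decel", "early dia"),
                 pos = 4, cex = 0.8)
  invisible(x)
}

#' Export a waveform as a two-column CSV (time, u_mean)
#'
#' @param waveform An [synth_waveform()] object.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_waveform_csv <- function(waveform, file) {
  stopifnot(inherits(waveform, "inlet_waveform"))
  utils::write.csv(data.frame(time = waveform$times,
                              u_mean = waveform$u_mean),
                   file, row.names = FALSE)
  invisible(file)
}
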