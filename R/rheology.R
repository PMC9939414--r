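#' Blood rheology parameters for the regularized Casson model
#'
#' Bundles the parameters of the hematocrit-dependent Casson viscosity law
#' used throughout the solver. The dynamic viscosity is
#' \deqn{\mu = 0.1\left[\sqrt{\eta} +
#'   \sqrt{\tau_y \frac{1 - e^{-m\dot\gamma}}{\dot\gamma}}\right]^2,}
#' with yield stress \eqn{\tau_y = (0.625 H)^3}. The leading 0.1 is read as
#' the poise-to-Pa.s conversion, so \code{eta} is the Casson plastic
#' viscosity in poise, \eqn{\tau_y} is in dyn/cm^2, and the returned
#' viscosity is in Pa.s. The exponential factor is a Papanastasiou-type
#' regularization that keeps \eqn{\mu} finite and continuous at zero shear.
#'
#' @param H Hematocrit (red-cell volume fraction), dimensionless in [0, 1).
#'   0.35 and 0.45 are representative adult female / male values.
#' @param eta Casson plastic viscosity in poise. The default 0.035 poise
#'   gives the standard high-shear blood viscosity of 3.5 mPa.s.
#' @param m Regularization time constant in seconds; larger values track
#'   the ideal (unregularized) Casson law more closely at low shear.
#' @param rho Blood density, kg/m^3.
#' @param newtonian If \code{TRUE}, force the yield stress to zero so the
#'   fluid is Newtonian with viscosity \code{0.1 * eta} Pa.s, regardless of
#'   \code{H}. Used for the analytic benchmark runs.
#'
#' @return An object of class \code{"rheology_params"}: a list with fields
#'   \code{H}, \code{eta}, \code{m}, \code{rho}, \code{newtonian} and the
#'   derived \code{tau_y} (dyn/cm^2).
#' @seealso [casson_viscosity()], [yield_stress()]
#' @export
#' @examples
#' rh <- rheology_params(H = 0.45)
#' casson_viscosity(c(1, 10, 100, 1000), rh)
rheology_params <- function(H = 0.45, eta = 0.035, m = 100, rho = 1060,
                            newtonian = FALSE) {
  stopifnot(is.numeric(H), length(H) == 1L, H >= 0, H < 1,
            is.numeric(eta), length(eta) == 1L, eta > 0,
            is.numeric(m), length(m) == 1L, m > 0,
            is.numeric(rho), length(rho) == 1L, rho > 0,
            is.logical(newtonian), length(newtonian) == 1L)
  structure(list(H = H, eta = eta, m = m, rho = rho,
                 newtonian = newtonian,
                 tau_y = if (newtonian) 0 else yield_stress(H)),
            class = "rheology_params")
}

#' @export
print.rheology_params <- function(x, ...) {
  cat("Casson blood rheology\n")
  cat(sprintf("  hematocrit H      : %.3f%s\n", x$H,
              if (x$newtonian) "  (newtonian switch ON: tau_y forced to 0)" else ""))
  cat(sprintf("  plastic visc. eta : %.4f poise (mu_inf = %.3f mPa.s)\n",
              x$eta, 100 * x$eta))
  cat(sprintf("  yield stress      : %.6f dyn/cm^2\n", x$tau_y))
  cat(sprintf("  regularization m  : %.1f s\n", x$m))
  cat(sprintf("  density rho       : %.0f kg/m^3\n", x$rho))
  invisible(x)
}

#' Casson yield stress as a function of hematocrit
#'
#' \eqn{\tau_y = (0.625 H)^3}, in dyn/cm^2 (the formula's native unit
#' system; the 0.1 prefactor of the viscosity law converts to SI).
#'
#' @param H Hematocrit fraction, in [0, 1). Vectorized.
#' @return Yield stress \eqn{\tau_y}, dyn/cm^2. Strictly increasing in H.
#' @export
#' @examples
#' yield_stress(c(0.35, 0.45))
yield_stress <- function(H) {
  if (!is.numeric(H) || any(!is.finite(H)) || any(H < 0) || any(H >= 1))
    stop("H must be a finite hematocrit fraction in [0, 1)")
  (0.625 * H)^3
}

#' Regularized Casson dynamic viscosity
#'
#' Evaluates the regularized Casson law (see [rheology_params()]) at the
#' given shear-rate magnitudes. Continuous at zero shear via the limit
#' \eqn{(1 - e^{-m\dot\gamma})/\dot\gamma \to m}, strictly decreasing in
#' \eqn{\dot\gamma} when \eqn{\tau_y > 0}, and tending to \code{0.1 * eta}
#' (the infinite-shear Newtonian plateau) as \eqn{\dot\gamma \to \infty}.
#'
#' @param gamma_dot Shear-rate magnitude(s), 1/s, non-negative. Vectorized.
#' @param params A [rheology_params()] object.
#' @return Dynamic viscosity, Pa.s, same length as \code{gamma_dot}.
#' @export
casson_viscosity <- function(gamma_dot, params) {
  stopifnot(inherits(params, "rheology_params"))
  if (!is.numeric(gamma_dot) || any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop("gamma_dot must be finite and non-negative")
  tau_y <- params$tau_y
  m <- params$m
  # (1 - exp(-m g))/g with its m limit at g = 0; expm1 keeps small-g accuracy
  reg <- ifelse(gamma_dot > 0, -expm1(-m * gamma_dot) / gamma_dot, m)
  0.1 * (sqrt(params$eta) + sqrt(tau_y * reg))^2
}

#' Shear-rate magnitude from a 2D velocity-gradient tensor
#'
#' \eqn{\dot\gamma = \sqrt{2\,D\!:\!D}} with
#' \eqn{D = \tfrac12(\nabla u + \nabla u^T)} the rate-of-strain tensor.
#' For a 2D field,
#' \eqn{\dot\gamma = \sqrt{2 u_x^2 + 2 v_y^2 + (u_y + v_x)^2}}.
#' Frame-invariant: rigid rotation (antisymmetric gradient) gives 0.
#'
#' @param dudx,dudy,dvdx,dvdy Velocity-gradient components, 1/s.
#'   Vectorized (arrays allowed; shapes must match).
#' @return Shear-rate magnitude \eqn{\dot\gamma \ge 0}, 1/s.
#' @export
#' @examples
#' shear_rate_magnitude(0, 3, 0, 0)        # simple shear: |k| = 3
#' shear_rate_magnitude(0, 1, -1, 0)       # rigid rotation: 0
#' shear_rate_magnitude(2, 0, 0, -2)       # pure extension: 2|a| = 4
shear_rate_magnitude <- function(dudx, dudy, dvdx, dvdy) {
  if (any(!is.finite(dudx)) || any(!is.finite(dudy)) ||
      any(!is.finite(dvdx)) || any(!is.finite(dvdy)))
    stop("velocity-gradient components must be finite")
  sqrt(2 * dudx^2 + 2 * dvdy^2 + (dudy + dvdx)^2)
}
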