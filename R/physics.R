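#' Number of beads in a microwheel of radius R
#'
#' The standard estimate is `n = (R/a)^2`; the optional hexagonal
#' close-packed variant multiplies by the 2D HCP density pi/(2 sqrt(3)) ~
#' 0.9069.
#'
#' @param R Wheel radius (m), vectorized.
#' @param params A `uw_params` object.
#' @param packing `"default"` for `n = (R/a)^2`, `"hcp"` for the close-packed
#'   estimate.
#' @return Bead count (dimensionless, not rounded).
#' @export
n_beads <- function(R, params, packing = c("default", "hcp")) {
  packing <- match.arg(packing)
  a <- params$bead$a
  if (any(R < a))
    uw_stop("wheel radius R must be at least one bead radius", "uw_invalid_radius")
  n <- (R / a)^2
  if (packing == "hcp") n <- n * .uw_hcp
  n
}

#' Microwheel rotation rate
#'
#' Balancing the magnetic torque `n nu mu0 chi'' H^2` against the rotational
#' viscous torque of a disk `32 eta omega R^3 / 3` gives
#' `omega = 3 n nu mu0 chi'' H^2 / (32 eta R^3)`. With `n = (R/a)^2` this
#' collapses to `omega = c / R`: rotation slows inversely with size. By
#' default the shipped calibration constant `c_omega` is used directly
#' (`omega = c_omega / R`); set `field$c_omega = NULL` to evaluate the
#' torque-balance formula with `chi_imag`.
#'
#' @param R Wheel radius (m), vectorized.
#' @param params A `uw_params` object.
#' @return Angular velocity omega (rad/s).
#' @examples
#' p <- default_params()
#' rotation_rate(c(10e-6, 20e-6), p)  # halves when R doubles
#' @export
rotation_rate <- function(R, params) {
  a <- params$bead$a
  if (any(R < a))
    uw_stop("wheel radius R must be at least one bead radius", "uw_invalid_radius")
  c_om <- params$field$c_omega
  if (!is.null(c_om)) return(c_om / R)
  n <- n_beads(R, params)
  nu <- 4 / 3 * pi * a^3
  H <- params$field$B / .uw_const$mu0
  3 * n * nu * .uw_const$mu0 * params$bead$chi_imag * H^2 /
    (32 * params$fluid$eta * R^3)
}

# electrostatic prefactor F0 = 4 pi eps eps0 a kappa zeta1 zeta2 (N); the
# sphere-wall repulsion is F_es(delta) = F0 exp(-kappa delta)
.f_es0 <- function(params) {
  f <- params$fluid
  4 * pi * f$eps_rel * .uw_const$eps0 * params$bead$a * f$debye_inv *
    f$zeta_particle * f$zeta_wall
}

# normal / parallel weight components (N) for radius R at incline phi (deg)
.weights <- function(R, phi_deg, params, packing = "default") {
  n <- n_beads(R, params, packing = packing)
  W <- bead_mass(params) * .uw_const$g * n
  list(n = n, W = W,
       W_y = W * cos(.deg2rad(phi_deg)),
       W_x = W * sin(.deg2rad(phi_deg)))
}

.check_incline <- function(phi_deg) {
  uw_check(all(phi_deg >= 0 & phi_deg < 90),
           "incline angle must satisfy 0 <= phi < 90 degrees")
}

#' Lubrication gap width on an incline
#'
#' The wheel rides on a fluid layer whose thickness is set by balancing the
#' normal load `W_y = m g n cos(phi)` against the screened electrostatic
#' wall repulsion `F_es = 4 pi eps eps0 a kappa zeta1 zeta2 exp(-kappa
#' delta)`. Solving and applying the shape factor `k1` gives the closed form
#' `delta = k1 kappa^-1 ln(4 pi eps eps0 a kappa zeta1 zeta2 / (m g n
#' cos(phi)))`.
#'
#' If the load exceeds the maximum available repulsion (log argument <= 1)
#' the wheel is pinned to the wall; this is signalled as a distinct
#' `uw_pinned_error`.
#'
#' @param R Wheel radius (m), vectorized.
#' @param phi Incline angle (degrees), in `[0, 90)`.
#' @param params A `uw_params` object.
#' @param k1 Gap shape factor; defaults to `params$fit$k1`.
#' @return Gap width delta (m).
#' @export
gap_width <- function(R, phi, params, k1 = params$fit$k1) {
  .check_incline(phi)
  w <- .weights(R, phi, params)
  arg <- .f_es0(params) / w$W_y
  if (any(arg <= 1))
    uw_stop("load exceeds maximum electrostatic repulsion: wheel pinned to wall",
            "uw_pinned_error")
  k1 / params$fluid$debye_inv * log(arg)
}

# drag denominator D = ln(2 (R + delta) / R) - (1/4) (R / (R + delta))^2 for
# the analytic cylinder-near-wall drag F_d = k2 8 pi a eta V / D
.drag_D <- function(R, delta) {
  log(2 * (R + delta) / R) - 0.25 * (R / (R + delta))^2
}

#' Microwheel translation velocity on an incline (closed form)
#'
#' Solves the propulsion-direction force balance `F_f - F_d - W_x = 0`,
#' where the wet-friction force `F_f = mu_k W_y` follows from equating the
#' frictional torque with the torque to shear the lubrication layer
#' (`mu_k = eta a R (omega R - V) / (delta W_y)`) and the drag is the
#' shape-corrected analytic cylinder drag. The balance is linear in `V`:
#'
#' `V = (eta a R^2 omega / delta - m g n sin(phi)) /
#'      (eta a R / delta + 8 pi k2 a eta / D)`
#'
#' with `D = ln(2(R+delta)/R) - (1/4)(R/(R+delta))^2`. The result is signed:
#' negative values mean the wheel slips backwards downhill while rolling,
#' the regime entered by large wheels on steep inclines.
#'
#' @param R Wheel radius (m), vectorized.
#' @param phi Incline angle (degrees), in `[0, 90)`.
#' @param params A `uw_params` object.
#' @param omega Angular velocity (rad/s); defaults to [rotation_rate()].
#' @return Translation velocity V (m/s), signed, never clamped.
#' @examples
#' p <- default_params()
#' wheel_velocity(60e-6, phi = 0, params = p)   # fast on the flat
#' wheel_velocity(60e-6, phi = 80, params = p)  # negative: slips downhill
#' @export
wheel_velocity <- function(R, phi, params, omega = NULL) {
  if (is.null(omega)) omega <- rotation_rate(R, params)
  delta <- gap_width(R, phi, params)
  w <- .weights(R, phi, params)
  eta <- params$fluid$eta
  a <- params$bead$a
  D <- .drag_D(R, delta)
  (eta * a * R^2 * omega / delta - w$W_x) /
    (eta * a * R / delta + 8 * pi * params$fit$k2 * a * eta / D)
}

#' Effective climbing angle under switchback actuation
#'
#' Alternating the heading by a switchback angle `phi_sb` lowers the
#' effective incline the wheel experiences:
#' `phi_eff = asin(sin(phi) cos(phi_sb))`. At phi = 80 deg a 35 deg
#' switchback gives phi_eff ~ 54 deg.
#'
#' @param phi Incline angle (degrees), in `[0, 90]`, vectorized.
#' @param phi_sb Switchback angle (degrees), in `[0, 90)`.
#' @return Effective incline (degrees); `<= phi`, with equality iff either
#'   angle is zero.
#' @export
effective_incline <- function(phi, phi_sb) {
  uw_check(all(phi >= 0 & phi <= 90), "phi must be in [0, 90] degrees")
  uw_check(all(phi_sb >= 0 & phi_sb < 90), "phi_sb must be in [0, 90) degrees")
  .rad2deg(asin(sin(.deg2rad(phi)) * cos(.deg2rad(phi_sb))))
}

#' Dimensionless groups of the bead-scale assembly physics
#'
#' Computes the Peclet number `Pe = 6 pi eta a^3 gdot / kT`, the dipole
#' strength `lambda = pi mu0 a^3 chi^2 H^2 / (9 kT)` and the Mason number
#' `Mn = 54 eta gdot / (mu0 chi^2 H^2) = Pe / lambda`, which gauges viscous
#' against magnetic forces and governs wheel growth and stability. The shear
#' rate may be given directly, or estimated at the wheel rim as
#' `gdot = omega R / l` with `l` a fluid velocity decay length; since
#' `omega ~ 1/R`, `Mn` is then nearly size-independent.
#'
#' @param params A `uw_params` object.
#' @param gamma_dot Shear rate (1/s). Either supply this, or all of `omega`,
#'   `R`, `l`.
#' @param omega,R,l Rim estimate inputs: angular velocity (rad/s), wheel
#'   radius (m), decay length (m).
#' @return A list of class `uw_dimensionless` with `Pe`, `lam`, `Mn`,
#'   `gamma_dot` and `l` (NA when not used).
#' @export
dimensionless_groups <- function(params, gamma_dot = NULL, omega = NULL,
                                 R = NULL, l = NULL) {
  if (is.null(gamma_dot)) {
    uw_check(!is.null(omega) && !is.null(R) && !is.null(l),
             "supply gamma_dot, or all of omega, R and l")
    uw_check(all(l > 0), "decay length l must be > 0")
    gamma_dot <- omega * R / l
  } else {
    l <- NA_real_
  }
  a <- params$bead$a
  chi <- params$bead$chi
  H <- params$field$B / .uw_const$mu0
  kT <- .uw_const$kB * params$fluid$T
  eta <- params$fluid$eta
  Pe <- 6 * pi * eta * a^3 * gamma_dot / kT
  lam <- pi * .uw_const$mu0 * a^3 * chi^2 * H^2 / (9 * kT)
  Mn <- 54 * eta * gamma_dot / (.uw_const$mu0 * chi^2 * H^2)
  structure(list(Pe = Pe, lam = lam, Mn = Mn, gamma_dot = gamma_dot, l = l),
            class = "uw_dimensionless")
}

#' Force breakdown for a rolling wheel
#'
#' Evaluates every term of the incline force balance at a given (or solved)
#' velocity: the weight and its components, the electrostatic support (equal
#' to the normal load at the solved gap, with `k1` absorbed into the
#' effective decay length), the drag, the wet-friction force and
#' coefficient, and the gap width. At `V = wheel_velocity(...)` the residual
#' `F_f - F_d - W_x` vanishes to round-off.
#'
#' @param R Wheel radius (m), vectorized.
#' @param phi Incline angle (degrees).
#' @param params A `uw_params` object.
#' @param omega Angular velocity (rad/s); default [rotation_rate()].
#' @param V Velocity (m/s); default [wheel_velocity()].
#' @return A data.frame of class `uw_forces` with columns `R`, `phi`, `W_total`,
#'   `W_x`, `W_y`, `F_es`, `F_d`, `F_f`, `mu_k`, `delta`, `V`, `omega`,
#'   `residual`.
#' @export
force_breakdown <- function(R, phi, params, omega = NULL, V = NULL) {
  if (is.null(omega)) omega <- rotation_rate(R, params)
  if (is.null(V)) V <- wheel_velocity(R, phi, params, omega = omega)
  delta <- gap_width(R, phi, params)
  w <- .weights(R, phi, params)
  eta <- params$fluid$eta
  a <- params$bead$a
  mu_k <- eta * a * R * (omega * R - V) / (delta * w$W_y)
  F_f <- mu_k * w$W_y
  F_d <- params$fit$k2 * 8 * pi * a * eta * V / .drag_D(R, delta)
  out <- data.frame(R = R, phi = phi, W_total = w$W, W_x = w$W_x, W_y = w$W_y,
                    F_es = w$W_y, F_d = F_d, F_f = F_f, mu_k = mu_k,
                    delta = delta, V = V, omega = omega,
                    residual = F_f - F_d - w$W_x)
  class(out) <- c("uw_forces", "data.frame")
  out
}
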