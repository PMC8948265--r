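#' Bead parameters
#'
#' Physical properties of a single superparamagnetic bead, the building block
#' of a microwheel. The bead volume `nu = (4/3) pi a^3` is always derived from
#' the radius, never stored.
#'
#' @param a Bead radius (m). Default 2.25e-6 (4.5 um diameter Dynabead-class
#'   particle).
#' @param rho_bead Bead density (kg/m^3). Default 1600.
#' @param chi Magnetic susceptibility (real part, dimensionless).
#' @param chi_imag Imaginary susceptibility chi'' (dimensionless), driving the
#'   magnetic torque. Not directly measurable from the shipped defaults; the
#'   default 0.0104 is calibrated so the torque-balance rotation rate matches
#'   the shipped `c_omega` (see [field_params()]).
#' @return A list of class `uw_bead_params`.
#' @seealso [uw_params()], [default_params()]
#' @export
bead_params <- function(a = 2.25e-6, rho_bead = 1600, chi = 1.0,
                        chi_imag = 0.0104) {
  uw_check(is.numeric(a) && length(a) == 1L && a > 0, "bead radius a must be > 0")
  uw_check(rho_bead > 0, "rho_bead must be > 0")
  uw_check(chi > 0, "chi must be > 0")
  uw_check(chi_imag >= 0, "chi_imag must be >= 0")
  structure(list(a = a, rho_bead = rho_bead, chi = chi, chi_imag = chi_imag),
            class = "uw_bead_params")
}

#' Fluid and surface-interaction parameters
#'
#' The suspending medium plus the electrostatic double-layer parameters that
#' set the lubrication gap: Debye parameter `kappa` (inverse screening
#' length) and the zeta potentials of particle and wall.
#'
#' @param eta Dynamic viscosity (Pa s).
#' @param rho_fluid Fluid density (kg/m^3); used for the buoyancy-corrected
#'   bead mass.
#' @param T Temperature (K).
#' @param eps_rel Relative permittivity of the medium.
#' @param debye_inv Inverse Debye length kappa (1/m). Default 5e7
#'   (kappa^-1 = 20 nm), an illustrative low-ionic-strength value.
#' @param zeta_particle,zeta_wall Zeta potentials (V) of bead and substrate.
#' @return A list of class `uw_fluid_params`.
#' @export
fluid_params <- function(eta = 1.0e-3, rho_fluid = 1000, T = 298,
                         eps_rel = 80, debye_inv = 5e7,
                         zeta_particle = 0.060, zeta_wall = 0.060) {
  uw_check(eta > 0, "eta must be > 0")
  uw_check(rho_fluid > 0, "rho_fluid must be > 0")
  uw_check(T > 0, "temperature must be > 0")
  uw_check(eps_rel > 0, "eps_rel must be > 0")
  uw_check(debye_inv > 0, "debye_inv must be > 0")
  structure(list(eta = eta, rho_fluid = rho_fluid, T = T, eps_rel = eps_rel,
                 debye_inv = debye_inv, zeta_particle = zeta_particle,
                 zeta_wall = zeta_wall),
            class = "uw_fluid_params")
}

#' Rotating-field parameters
#'
#' The applied field is entered as a flux density `B` (what a gaussmeter
#' reads); the field strength `H = B / mu0` is used inside the formulas.
#'
#' @param B Flux density (T). Default 3.7e-3 (3.7 mT).
#' @param freq Field rotation frequency (Hz). Default 40.
#' @param camber_deg Camber (tilt) angle of the wheel plane relative to the
#'   surface normal (degrees). Held constant; informational only — the load
#'   model deliberately omits camber dependence.
#' @param c_omega Calibrated rotation-rate constant (m rad/s) so that
#'   `omega = c_omega / R`. When `NULL`, the torque-balance formula with
#'   `chi_imag` is used instead (which also yields `omega = c/R` when
#'   `n = (R/a)^2`). Default 1e-4.
#' @return A list of class `uw_field_params`.
#' @export
field_params <- function(B = 3.7e-3, freq = 40, camber_deg = 30,
                         c_omega = 1e-4) {
  uw_check(B > 0, "B must be > 0")
  uw_check(freq > 0, "freq must be > 0")
  uw_check(is.null(c_omega) || c_omega > 0, "c_omega must be > 0 or NULL")
  structure(list(B = B, freq = freq, camber_deg = camber_deg,
                 c_omega = c_omega),
            class = "uw_field_params")
}

#' Shape-correction fit parameters
#'
#' `k1` rescales the sphere-wall gap width for the non-circular, spinning
#' wheel; `k2` rescales the cylinder drag for the bumpy bead-cluster surface.
#' The shipped values are the experimentally fitted ones (k1 = 1.50,
#' k2 = 3.11).
#'
#' @param k1 Gap-width shape factor (> 0).
#' @param k2 Drag shape factor (> 0).
#' @return A list of class `uw_fit_params`.
#' @export
fit_params <- function(k1 = 1.50, k2 = 3.11) {
  uw_check(k1 > 0, "k1 must be > 0")
  uw_check(k2 > 0, "k2 must be > 0")
  structure(list(k1 = k1, k2 = k2), class = "uw_fit_params")
}

#' Full model parameter set
#'
#' Bundles bead, fluid, field and fit parameters. All physics functions take
#' such a bundle.
#'
#' @param bead A [bead_params()] object.
#' @param fluid A [fluid_params()] object.
#' @param field A [field_params()] object.
#' @param fit A [fit_params()] object.
#' @param buoyant Logical; if `TRUE` (default) the per-bead mass is
#'   buoyancy-corrected, `m = (rho_bead - rho_fluid) nu`, since the wheels
#'   operate submerged. `FALSE` gives the raw mass `rho_bead * nu`.
#' @return A list of class `uw_params`.
#' @examples
#' p <- default_params()
#' wheel_velocity(10e-6, phi = 40, params = p)
#' @export
uw_params <- function(bead = bead_params(), fluid = fluid_params(),
                      field = field_params(), fit = fit_params(),
                      buoyant = TRUE) {
  uw_check(inherits(bead, "uw_bead_params"), "bead must be bead_params()")
  uw_check(inherits(fluid, "uw_fluid_params"), "fluid must be fluid_params()")
  uw_check(inherits(field, "uw_field_params"), "field must be field_params()")
  uw_check(inherits(fit, "uw_fit_params"), "fit must be fit_params()")
  structure(list(bead = bead, fluid = fluid, field = field, fit = fit,
                 buoyant = isTRUE(buoyant)),
            class = "uw_params")
}

#' Shipped illustrative default parameters
#'
#' The default parameter set: 4.5 um beads (a = 2.25 um, rho = 1600 kg/m^3)
#' in water-like fluid at 298 K, a 3.7 mT / 40 Hz rotating field with 30
#' degree camber, and the fitted shape factors k1 = 1.50, k2 = 3.11. The
#' electrostatic parameters (kappa^-1 = 20 nm, |zeta| = 60 mV) and the
#' rotation calibration (c_omega = 1e-4 m rad/s) are illustrative: chosen
#' once to reproduce the qualitative regimes (tens of um/s on the flat,
#' wheels larger than ~35 um slipping backwards at 80 degrees) rather than
#' fitted to any measurement. All values are overridable.
#'
#' @return A `uw_params` object.
#' @export
default_params <- function() uw_params()

#' Per-bead mass used in the load terms (kg)
#'
#' @param params A `uw_params` object.
#' @return Scalar mass (kg), buoyancy-corrected unless `params$buoyant` is
#'   `FALSE`.
#' @export
bead_mass <- function(params) {
  nu <- 4 / 3 * pi * params$bead$a^3
  rho <- params$bead$rho_bead - if (params$buoyant) params$fluid$rho_fluid else 0
  uw_check(rho > 0, "effective bead density must be positive")
  rho * nu
}

# ---- config I/O -------------------------------------------------------------

# Boundary units for structured-text configs: um, mT, Hz, mV, nm, degrees.
.uw_schema <- list(
  bead  = c("a_um", "rho_bead_kg_m3", "chi", "chi_imag"),
  fluid = c("eta_mPa_s", "rho_fluid_kg_m3", "T_K", "eps_rel",
            "debye_length_nm", "zeta_particle_mV", "zeta_wall_mV"),
  field = c("B_mT", "freq_Hz", "camber_deg", "c_omega"),
  fit   = c("k1", "k2"),
  options = c("buoyant")
)

#' Read a model parameter config (JSON)
#'
#' Configs use field-friendly boundary units (um, mT, Hz, mV, nm, degrees)
#' and are converted to SI on load. The schema is strict: unknown sections or
#' keys are rejected. Missing keys fall back to the shipped defaults.
#'
#' @param path Path to a JSON file with optional sections `bead`, `fluid`,
#'   `field`, `fit`, `options`.
#' @return A `uw_params` object.
#' @seealso [write_params()]
#' @export
read_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), names(.uw_schema))
  if (length(bad))
    uw_stop(paste0("unknown config section(s): ", paste(bad, collapse = ", ")),
            "uw_config_error")
  for (sec in names(cfg)) {
    badk <- setdiff(names(cfg[[sec]]), .uw_schema[[sec]])
    if (length(badk))
      uw_stop(paste0("unknown key(s) in [", sec, "]: ",
                     paste(badk, collapse = ", ")), "uw_config_error")
  }
  g <- function(sec, key, default) {
    v <- cfg[[sec]][[key]]
    if (is.null(v)) default else v
  }
  bead <- bead_params(
    a = g("bead", "a_um", 2.25) * 1e-6,
    rho_bead = g("bead", "rho_bead_kg_m3", 1600),
    chi = g("bead", "chi", 1.0),
    chi_imag = g("bead", "chi_imag", 0.0104))
  fluid <- fluid_params(
    eta = g("fluid", "eta_mPa_s", 1.0) * 1e-3,
    rho_fluid = g("fluid", "rho_fluid_kg_m3", 1000),
    T = g("fluid", "T_K", 298),
    eps_rel = g("fluid", "eps_rel", 80),
    debye_inv = 1 / (g("fluid", "debye_length_nm", 20) * 1e-9),
    zeta_particle = g("fluid", "zeta_particle_mV", 60) * 1e-3,
    zeta_wall = g("fluid", "zeta_wall_mV", 60) * 1e-3)
  field <- field_params(
    B = g("field", "B_mT", 3.7) * 1e-3,
    freq = g("field", "freq_Hz", 40),
    camber_deg = g("field", "camber_deg", 30),
    c_omega = g("field", "c_omega", 1e-4))
  fit <- fit_params(k1 = g("fit", "k1", 1.50), k2 = g("fit", "k2", 3.11))
  uw_params(bead, fluid, field, fit, buoyant = g("options", "buoyant", TRUE))
}

#' Write a model parameter config (JSON)
#'
#' Inverse of [read_params()]; emits boundary units.
#'
#' @param params A `uw_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  cfg <- list(
    bead = list(a_um = params$bead$a * 1e6,
                rho_bead_kg_m3 = params$bead$rho_bead,
                chi = params$bead$chi, chi_imag = params$bead$chi_imag),
    fluid = list(eta_mPa_s = params$fluid$eta * 1e3,
                 rho_fluid_kg_m3 = params$fluid$rho_fluid,
                 T_K = params$fluid$T, eps_rel = params$fluid$eps_rel,
                 debye_length_nm = 1e9 / params$fluid$debye_inv,
                 zeta_particle_mV = params$fluid$zeta_particle * 1e3,
                 zeta_wall_mV = params$fluid$zeta_wall * 1e3),
    field = list(B_mT = params$field$B * 1e3, freq_Hz = params$field$freq,
                 camber_deg = params$field$camber_deg,
                 c_omega = params$field$c_omega),
    fit = list(k1 = params$fit$k1, k2 = params$fit$k2),
    options = list(buoyant = params$buoyant))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
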