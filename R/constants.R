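# Physical constants (SI). CODATA 2018 values.
.uw_const <- list(
  mu0  = 4e-7 * pi,          # vacuum permeability (T m / A)
  eps0 = 8.8541878128e-12,   # vacuum permittivity (F / m)
  kB   = 1.380649e-23,       # Boltzmann constant (J / K)
  g    = 9.80665             # standard gravity (m / s^2)
)

# 2D hexagonal close packing density pi / (2 sqrt(3)); used by the optional
# HCP bead-count estimate n = 0.9069 (R/a)^2.
.uw_hcp <- pi / (2 * sqrt(3))

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Signal a classed uwheel error
#'
#' All package errors carry class `uw_error` plus a specific subclass so
#' callers can distinguish, e.g., a pinned wheel (`uw_pinned_error`) from a
#' bad parameter (`uw_domain_error`).
#' @noRd
uw_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "uw_error", "error", "condition")))
}

uw_check <- function(ok, msg, class = "uw_domain_error") {
  if (!all(ok)) uw_stop(msg, class)
  invisible(TRUE)
}
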