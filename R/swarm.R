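#' Swarm mode definition
#'
#' A swarm mode is a field-actuation pattern that selects a characteristic
#' microwheel size distribution and collective kinematics. Four modes are
#' supported: `rolling` (largest wheels, fastest mass transport),
#' `switchback` (mid-size wheels, climbs steep inclines by alternating
#' heading), `flipping` (smallest wheels, 4.5-20 um, wide-area deposition)
#' and `corkscrew` (mid-size, helical motion for mechanical action).
#'
#' Radius distributions are truncated log-normals in um; the shipped
#' location/scale values are illustrative (chosen to reproduce the ranked
#' spreads of the modes), while the truncation bounds are physical: the lower
#' bound 4.5 um is the single-bead scale and the rolling upper bound 60 um is
#' the maximum steady-state wheel size at 3.7 mT.
#'
#' @param name One of `"rolling"`, `"switchback"`, `"flipping"`,
#'   `"corkscrew"`.
#' @param switchback_angle Switchback heading half-angle (deg); only
#'   meaningful for (and defaulted by) the switchback mode, 35 deg.
#' @param dist Optional override list with elements `meanlog`, `sdlog`
#'   (log-um scale) and `lower_um`, `upper_um` truncation bounds.
#' @param speed_factor Mode-level translation multiplier applied on top of
#'   the single-wheel model (default 1), a hook for the corkscrew/flipping
#'   slowdown which is described but not parameterized.
#' @return A list of class `uw_mode`.
#' @export
swarm_mode <- function(name = c("rolling", "switchback", "flipping", "corkscrew"),
                       switchback_angle = NULL, dist = NULL,
                       speed_factor = 1) {
  name <- match.arg(name)
  defaults <- list(
    rolling    = list(meanlog = log(20), sdlog = 0.60, lower_um = 4.5, upper_um = 60),
    switchback = list(meanlog = log(15), sdlog = 0.50, lower_um = 4.5, upper_um = 40),
    corkscrew  = list(meanlog = log(12), sdlog = 0.50, lower_um = 4.5, upper_um = 35),
    flipping   = list(meanlog = log(9),  sdlog = 0.40, lower_um = 4.5, upper_um = 20))
  d <- utils::modifyList(defaults[[name]], as.list(dist %||% list()))
  uw_check(d$lower_um >= 4.5, "truncation lower bound must be >= 4.5 um (single-bead scale)")
  uw_check(d$upper_um > d$lower_um, "upper truncation must exceed lower")
  if (name == "switchback") {
    switchback_angle <- switchback_angle %||% 35
    uw_check(switchback_angle >= 0 && switchback_angle < 90,
             "switchback angle must be in [0, 90) degrees")
  } else {
    uw_check(is.null(switchback_angle),
             "switchback_angle is only set for switchback mode")
  }
  uw_check(speed_factor > 0, "speed_factor must be > 0")
  structure(list(name = name, switchback_angle = switchback_angle, dist = d,
                 speed_factor = speed_factor),
            class = "uw_mode")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# truncated log-normal sampler (inverse CDF)
.rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  p <- stats::runif(n, stats::plnorm(lower, meanlog, sdlog),
                    stats::plnorm(upper, meanlog, sdlog))
  stats::qlnorm(p, meanlog, sdlog)
}

#' Mass of a single microwheel
#'
#' `mass = n * m_bead` with the bead count from the radius, `n = (R/a)^2`
#' (optionally the hexagonally close-packed estimate, 0.9069 of that).
#' The per-bead mass is buoyancy-corrected unless the parameter set says
#' otherwise.
#'
#' @param R Wheel radius (m), vectorized.
#' @param params A `uw_params` object.
#' @param packing `"default"` or `"hcp"`.
#' @return Mass (kg).
#' @export
wheel_mass <- function(R, params, packing = c("default", "hcp")) {
  n_beads(R, params, packing = match.arg(packing)) * bead_mass(params)
}

#' Construct a swarm state
#'
#' A swarm is a weighted collection of independent wheels with a mode label.
#' Wheel-wheel interactions are ignored; dispersion arises from velocity
#' heterogeneity alone.
#'
#' @param wheels A data.frame with columns `R` (m) and optionally `n`,
#'   `mass` (kg), `omega` (rad/s), `x` (m), `alive`, `branch`, `lost_to`;
#'   missing columns are derived from `R` via the physics model.
#' @param mode A [swarm_mode()] object.
#' @param params A `uw_params` object used to derive missing columns.
#' @param t Swarm clock (s), default 0.
#' @return A list of class `uw_swarm` with elements `wheels`, `mode`, `t`,
#'   `total_mass`.
#' @export
uw_swarm <- function(wheels, mode = swarm_mode("rolling"),
                     params = default_params(), t = 0) {
  uw_check(is.data.frame(wheels) && nrow(wheels) > 0 && "R" %in% names(wheels),
           "wheels must be a nonempty data.frame with column R")
  w <- wheels
  if (is.null(w$n)) w$n <- n_beads(w$R, params)
  if (is.null(w$mass)) w$mass <- wheel_mass(w$R, params)
  if (is.null(w$omega)) w$omega <- rotation_rate(w$R, params)
  if (is.null(w$x)) w$x <- 0
  if (is.null(w$alive)) w$alive <- TRUE
  if (is.null(w$branch)) w$branch <- NA_character_
  if (is.null(w$lost_to)) w$lost_to <- NA_character_
  if (is.null(w$wheel_id)) w$wheel_id <- seq_len(nrow(w))
  uw_check(all(w$mass > 0), "wheel masses must be positive")
  uw_check(all(is.finite(w$x)), "wheel positions must be finite")
  structure(list(wheels = w, mode = mode, t = t, total_mass = sum(w$mass)),
            class = "uw_swarm")
}

#' @export
print.uw_swarm <- function(x, ...) {
  al <- sum(x$wheels$alive)
  cat(sprintf("<uw_swarm> %s mode: %d wheels (%d alive), t = %.1f s, mass %.3g kg\n",
              x$mode$name, nrow(x$wheels), al, x$t, x$total_mass))
  cat(sprintf("  R range %.1f-%.1f um\n", min(x$wheels$R) * 1e6,
              max(x$wheels$R) * 1e6))
  invisible(x)
}

#' Mode-effective wheel velocity
#'
#' The single-wheel velocity adjusted for the swarm mode's kinematics:
#' switchback wheels experience the lowered effective incline
#' `asin(sin(phi) cos(phi_sb))` but pay the zig-zag path-lengthening factor
#' `cos(phi_sb)` on forward progress; other modes apply their
#' `speed_factor`.
#'
#' @param R Wheel radius (m), vectorized.
#' @param phi Incline angle (degrees).
#' @param mode A [swarm_mode()] object.
#' @param params A `uw_params` object.
#' @return Forward velocity along the mean heading (m/s), signed.
#' @export
mode_velocity <- function(R, phi, mode, params) {
  if (mode$name == "switchback") {
    phi_eff <- effective_incline(phi, mode$switchback_angle)
    wheel_velocity(R, phi_eff, params) * cos(.deg2rad(mode$switchback_angle))
  } else {
    wheel_velocity(R, phi, params) * mode$speed_factor
  }
}

#' Predicted spatial mass profile of a swarm at time t
#'
#' On a uniform incline each wheel advances ballistically at its
#' mode-effective velocity, `x_i = V(R_i, phi) * t`; binning the wheel
#' masses gives the predicted time-dependent mass distribution. Mass is
#' conserved: the bin fractions sum to the currently-alive mass fraction
#' (1 before any clipping), and the area under every mode's profile at fixed
#' t is therefore equal.
#'
#' @param swarm A `uw_swarm` object.
#' @param t Time (s), `>= 0`.
#' @param phi Uniform incline angle (degrees). Default 0.
#' @param params A `uw_params` object.
#' @param breaks Number of bins (scalar) or an explicit vector of bin edges
#'   (m) covering all wheel positions.
#' @return A list of class `uw_mass_profile` with `bin_edges` (m),
#'   `mass_fraction` (per bin, normalized by total swarm mass) and `t`.
#' @export
predict_mass_profile <- function(swarm, t, phi = 0, params = default_params(),
                                 breaks = 50) {
  uw_check(t >= 0, "t must be >= 0")
  w <- swarm$wheels[swarm$wheels$alive, ]
  x <- mode_velocity(w$R, phi, swarm$mode, params) * t
  if (length(breaks) == 1L) {
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5e-3, 0.5e-3)
    edges <- seq(rng[1] - 1e-12, rng[2] + 1e-12, length.out = breaks + 1L)
  } else {
    edges <- breaks
    uw_check(min(x) >= edges[1] && max(x) <= edges[length(edges)],
             "explicit bin edges must cover all wheel positions")
  }
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- vapply(seq_len(length(edges) - 1L),
                 function(i) sum(w$mass[idx == i]), numeric(1))
  structure(list(bin_edges = edges, mass_fraction = mass / swarm$total_mass,
                 t = t),
            class = "uw_mass_profile")
}

#' Mass-weighted centroid velocity of a swarm
#'
#' The swarm's bulk (center-of-mass) speed on a uniform incline: the
#' mass-weighted mean of the mode-effective per-wheel velocities over alive
#' wheels. Since larger wheels both carry more mass and translate faster,
#' modes with larger component wheels yield higher centroid velocities on
#' the flat.
#'
#' @param swarm A `uw_swarm` object.
#' @param phi Incline angle (degrees).
#' @param params A `uw_params` object.
#' @return Centroid velocity (m/s), signed.
#' @export
centroid_velocity <- function(swarm, phi, params = default_params()) {
  w <- swarm$wheels[swarm$wheels$alive, ]
  if (nrow(w) == 0) uw_stop("swarm has no alive wheels", "uw_empty_swarm")
  V <- mode_velocity(w$R, phi, swarm$mode, params)
  sum(w$mass * V) / sum(w$mass)
}

#' Read / write per-wheel swarm tables (CSV)
#'
#' Round-trip stable CSV interchange for tracked or generated swarms.
#' Columns: `wheel_id`, `R_um`, `mass_kg`, `x_mm`, `branch`, `alive`.
#'
#' @param swarm A `uw_swarm` object.
#' @param path CSV path.
#' @param mode,params Used on read to rebuild the swarm object.
#' @return `write_swarm_csv` returns `path` invisibly; `read_swarm_csv`
#'   returns a `uw_swarm`.
#' @export
write_swarm_csv <- function(swarm, path) {
  w <- swarm$wheels
  utils::write.csv(data.frame(wheel_id = w$wheel_id, R_um = w$R * 1e6,
                              mass_kg = w$mass, x_mm = w$x * 1e3,
                              branch = w$branch, alive = w$alive),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_swarm_csv
#' @export
read_swarm_csv <- function(path, mode = swarm_mode("rolling"),
                           params = default_params()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wheel_id", "R_um", "mass_kg", "x_mm", "branch", "alive")
  uw_check(all(need %in% names(d)),
           paste("swarm CSV must have columns:", paste(need, collapse = ", ")),
           "uw_format_error")
  uw_swarm(data.frame(wheel_id = d$wheel_id, R = d$R_um * 1e-6,
                      mass = d$mass_kg, x = d$x_mm * 1e-3,
                      branch = as.character(d$branch), alive = d$alive),
           mode = mode, params = params)
}
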