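# Shared fixtures: everything is built in code at test time.

p_def <- default_params()

# single-branch straight network with piecewise-linear incline knots
make_straight_net <- function(x_mm, phi_deg, target = "b0") {
  n <- length(x_mm)
  kind <- c(rep("waypoint", n - 1), "terminal")
  j <- data.frame(id = paste0("j", seq_len(n)), branch = "b0",
                  x = x_mm * 1e-3, phi_deg = phi_deg, kind = kind,
                  stringsAsFactors = FALSE)
  uw_network(j, target = target)
}

# two-turn toy tree: trunk -> T1 (exit brA / continue t2) -> T2 (brB / brC),
# flat throughout, parallel channel annotated at T1
make_toy_net <- function(par_mm = numeric(0), target = "brB") {
  mk <- function(id, branch, x_mm, kind, children = character(0),
                 par = numeric(0)) {
    list(id = id, branch = branch, x = x_mm * 1e-3, phi_deg = 0, kind = kind,
         children = children, parallel_offsets = par * 1e-3)
  }
  rows <- list(
    mk("start", "trunk", 0, "waypoint"),
    mk("T1", "trunk", 5, "turn", c("brA", "t2"), par = par_mm),
    mk("brA_a", "brA", 5, "waypoint"), mk("brA_end", "brA", 8, "terminal"),
    mk("t2_a", "t2", 5, "waypoint"),
    mk("T2", "t2", 9, "turn", c("brB", "brC")),
    mk("brB_a", "brB", 9, "waypoint"), mk("brB_end", "brB", 13, "terminal"),
    mk("brC_a", "brC", 9, "waypoint"), mk("brC_end", "brC", 12, "terminal"))
  j <- data.frame(id = vapply(rows, `[[`, "", "id"),
                  branch = vapply(rows, `[[`, "", "branch"),
                  x = vapply(rows, `[[`, 0, "x"),
                  phi_deg = vapply(rows, `[[`, 0, "phi_deg"),
                  kind = vapply(rows, `[[`, "", "kind"),
                  stringsAsFactors = FALSE)
  j$children <- lapply(rows, `[[`, "children")
  j$parallel_offsets <- lapply(rows, `[[`, "parallel_offsets")
  uw_network(j, target = target)
}

# swarm with hand-set radii (m), all at x = 0
make_swarm <- function(R, mode = swarm_mode("rolling"), params = p_def) {
  uw_swarm(data.frame(R = R), mode = mode, params = params)
}

# independent scalar evaluation of the rotation-rate torque balance,
# term by term (oracle for rotation_rate with c_omega = NULL)
oracle_omega <- function(R, a, eta, B, chi_imag) {
  mu0 <- 4e-7 * pi
  n <- (R / a)^2
  nu <- 4 / 3 * pi * a^3
  H <- B / mu0
  torque_mag <- n * nu * mu0 * chi_imag * H^2
  3 * torque_mag / (32 * eta * R^3)
}

# bracketed root-find on the normal force balance F_es(delta) = W_y (oracle
# for the gap-width closed form at k1 = 1)
oracle_gap <- function(R, phi_deg, params) {
  f <- params$fluid
  F0 <- 4 * pi * f$eps_rel * 8.8541878128e-12 * params$bead$a * f$debye_inv *
    f$zeta_particle * f$zeta_wall
  m <- (params$bead$rho_bead - f$rho_fluid) * 4 / 3 * pi * params$bead$a^3
  Wy <- m * 9.80665 * (R / params$bead$a)^2 * cos(phi_deg * pi / 180)
  uniroot(function(d) F0 * exp(-f$debye_inv * d) - Wy,
          c(1e-12, 1e-4), tol = 1e-18)$root
}

# brute-force root of the propulsion force balance F_f - F_d - W_x = 0
# (oracle for the closed-form wheel velocity)
oracle_velocity <- function(R, phi_deg, params) {
  eta <- params$fluid$eta
  a <- params$bead$a
  om <- rotation_rate(R, params)
  del <- gap_width(R, phi_deg, params)
  m <- (params$bead$rho_bead - params$fluid$rho_fluid) * 4 / 3 * pi * a^3
  Wx <- m * 9.80665 * (R / a)^2 * sin(phi_deg * pi / 180)
  D <- log(2 * (R + del) / R) - 0.25 * (R / (R + del))^2
  bal <- function(V) eta * a * R * (om * R - V) / del -
    params$fit$k2 * 8 * pi * a * eta * V / D - Wx
  uniroot(bal, c(-1, 1), tol = 1e-16)$root
}
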