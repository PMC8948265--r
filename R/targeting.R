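#' Targeting simulation configuration
#'
#' @param dt Euler time step (s). Default 0.1.
#' @param sigma_keep Half-width multiplier of the keep/loss windows at turns,
#'   in units of the swarm's mass-weighted positional standard deviation.
#'   Default 0.5.
#' @param collect_advance Collection distance (m): after the final turn the
#'   swarm is integrated until its mass-weighted mean advances this far, and
#'   all remaining mass counts as delivered. Default 1e-3 (1 mm).
#' @param max_time Wall-clock cap on the simulation (s). Default 600 (10
#'   min, the experimental actuation limit).
#' @param stall_steps Number of consecutive steps with no forward-moving
#'   alive wheel, before collection, that triggers a `stalled` termination.
#'   Default 10.
#' @param parallel_precedence If `TRUE` (default) a wheel inside both the
#'   keep window and a parallel-channel window is lost (conservative
#'   reading); if `FALSE` the keep window wins.
#' @return A list of class `uw_sim_config`.
#' @export
sim_config <- function(dt = 0.1, sigma_keep = 0.5, collect_advance = 1e-3,
                       max_time = 600, stall_steps = 10,
                       parallel_precedence = TRUE) {
  uw_check(dt > 0, "dt must be > 0")
  uw_check(sigma_keep > 0, "sigma_keep must be > 0")
  uw_check(collect_advance > 0, "collect_advance must be > 0")
  uw_check(max_time >= dt, "max_time must be >= dt")
  structure(list(dt = dt, sigma_keep = sigma_keep,
                 collect_advance = collect_advance, max_time = max_time,
                 stall_steps = stall_steps,
                 parallel_precedence = isTRUE(parallel_precedence)),
            class = "uw_sim_config")
}

#' One Euler step of swarm advection along a path
#'
#' Each alive wheel advances by `V(R_i, phi(x_i)) * dt`, with the incline
#' evaluated at its current position from the path's piecewise-linear
#' incline function. Negative velocities move wheels backwards; positions
#' are floored at x = 0 (the injection site is a wall). Dead wheels are
#' untouched.
#'
#' @param swarm A `uw_swarm`.
#' @param net A `uw_network`.
#' @param path A `uw_path`.
#' @param params A `uw_params` object.
#' @param dt Time step (s).
#' @return The advanced `uw_swarm` (clock moved by `dt`).
#' @export
advance_step <- function(swarm, net, path, params, dt = 0.1) {
  al <- swarm$wheels$alive
  if (any(al)) {
    x <- swarm$wheels$x[al]
    phi <- .incline_lookup(path, x)
    V <- .signed_velocity(swarm$wheels$R[al], phi, swarm$mode, params)
    swarm$wheels$x[al] <- pmax(0, x + V * dt)
  }
  swarm$t <- swarm$t + dt
  swarm
}

# mode velocity allowing negative inclines (downhill): the model is defined
# for phi in [0, 90); a downhill segment is the same wheel rolling with the
# parallel weight component aiding rather than opposing motion, i.e.
# V(-phi) = V at incline |phi| with the sign of W_x flipped
.signed_velocity <- function(R, phi, mode, params) {
  up <- phi >= 0
  V <- numeric(length(R))
  if (any(up)) V[up] <- mode_velocity(R[up], phi[up], mode, params)
  if (any(!up)) {
    p <- abs(phi[!up])
    omega <- rotation_rate(R[!up], params)
    delta <- gap_width(R[!up], p, params)
    w <- .weights(R[!up], p, params)
    eta <- params$fluid$eta; a <- params$bead$a
    D <- .drag_D(R[!up], delta)
    Vdown <- (eta * a * R[!up]^2 * omega / delta + w$W_x) /
      (eta * a * R[!up] / delta + 8 * pi * params$fit$k2 * a * eta / D)
    sf <- if (mode$name == "switchback") cos(.deg2rad(mode$switchback_angle)) else mode$speed_factor
    V[!up] <- Vdown * sf
  }
  V
}

#' Mass-weighted centroid and standard deviation of a swarm
#'
#' `xbar = sum(m_i x_i) / sum(m_i)` and
#' `sigma = sqrt(sum(m_i (x_i - xbar)^2) / sum(m_i))` over alive wheels.
#' The centroid steers the swarm: turns fire when it passes the turn
#' location, and sigma sets the clipping windows.
#'
#' @param swarm A `uw_swarm`.
#' @return Named numeric vector `c(centroid = , sigma = )` (m).
#' @export
centroid_and_sigma <- function(swarm) {
  w <- swarm$wheels[swarm$wheels$alive, ]
  if (nrow(w) == 0) uw_stop("swarm has no alive wheels", "uw_empty_swarm")
  m <- w$mass
  xbar <- sum(m * w$x) / sum(m)
  sigma <- sqrt(sum(m * (w$x - xbar)^2) / sum(m))
  c(centroid = xbar, sigma = sigma)
}

#' Clip a swarm at a turn
#'
#' Implements the turn bookkeeping of the targeting model: when the swarm
#' centroid passes a turn, only wheels within `sigma_keep * sigma` of the
#' turn point continue; wheels within the same window of any parallel
#' (adjacent untargeted) channel mouth are lost to that channel; all other
#' non-survivors are lost at the turn. If `sigma = 0` the swarm is
#' perfectly grouped and every alive wheel survives.
#'
#' @param swarm A `uw_swarm`.
#' @param turn_x Arc position of the turn (m).
#' @param parallel_offsets Numeric vector of parallel-channel mouth
#'   positions (m); may be empty.
#' @param sigma_keep Window half-width multiplier. Default 0.5.
#' @param parallel_precedence See [sim_config()].
#' @param label Label used in the `lost_to` bookkeeping (e.g. junction id).
#' @return The clipped `uw_swarm`: non-survivors get `alive = FALSE` and
#'   `lost_to` set to `"turn:<label>"` or `"parallel:<label>"`.
#' @export
clip_at_turn <- function(swarm, turn_x, parallel_offsets = numeric(0),
                         sigma_keep = 0.5, parallel_precedence = TRUE,
                         label = "turn") {
  cs <- centroid_and_sigma(swarm)
  sigma <- cs[["sigma"]]
  al <- swarm$wheels$alive
  if (sigma == 0) return(swarm)
  x <- swarm$wheels$x
  keep <- abs(x - turn_x) <= sigma_keep * sigma
  par_hit <- rep(FALSE, length(x))
  for (p in parallel_offsets) par_hit <- par_hit | abs(x - p) <= sigma_keep * sigma
  survive <- if (parallel_precedence) keep & !par_hit else keep
  lost_par <- al & !survive & par_hit
  lost_turn <- al & !survive & !par_hit
  swarm$wheels$alive[al & !survive] <- FALSE
  swarm$wheels$lost_to[lost_par] <- paste0("parallel:", label)
  swarm$wheels$lost_to[lost_turn] <- paste0("turn:", label)
  swarm
}

#' Simulate swarm targeting through a branching network
#'
#' The complete targeting procedure: the swarm starts at x = 0 and is Euler
#' integrated (time step `dt`) along the planned path, with the incline
#' evaluated at each wheel's position every step. Each time the
#' mass-weighted centroid passes the next turn on the path, the swarm is
#' clipped ([clip_at_turn()]). After the final turn the swarm is integrated
#' until the centroid advances `collect_advance` (1 mm), and all remaining
#' alive mass counts as successfully delivered.
#'
#' The run terminates `"reached"` on successful collection, `"timed_out"`
#' if the clock exceeds `max_time`, or `"stalled"` if no alive wheel moves
#' forward for `stall_steps` consecutive steps before collection (the
#' all-slip regime). The simulation is deterministic: identical inputs give
#' bit-identical results.
#'
#' @param swarm A `uw_swarm` (wheels at x = 0, all alive).
#' @param net A `uw_network`.
#' @param path A `uw_path`; default `find_path(net)`.
#' @param params A `uw_params` object.
#' @param config A [sim_config()].
#' @return A list of class `uw_targeting_result`: `efficiency` (delivered
#'   mass fraction), `per_junction_losses` (data.frame `junction_id`,
#'   `lost_turn`, `lost_parallel` mass fractions), `residual` (in-transit
#'   mass fraction at termination), `termination`, `trace` (data.frame `t`,
#'   `centroid`, `sigma`, `alive_mass`), and the final `swarm`.
#' @export
simulate_targeting <- function(swarm, net, path = NULL,
                               params = default_params(),
                               config = sim_config()) {
  if (is.null(path)) path <- find_path(net)
  total <- swarm$total_mass
  trace_t <- trace_c <- trace_s <- trace_m <- numeric(0)
  stall_count <- 0L
  termination <- NULL

  record <- function(sw) {
    cs <- centroid_and_sigma(sw)
    trace_t <<- c(trace_t, sw$t)
    trace_c <<- c(trace_c, cs[["centroid"]])
    trace_s <<- c(trace_s, cs[["sigma"]])
    trace_m <<- c(trace_m, sum(sw$wheels$mass[sw$wheels$alive]))
    cs
  }
  step_forward <- function(sw, check_stall) {
    al <- sw$wheels$alive
    x <- sw$wheels$x[al]
    phi <- .incline_lookup(path, x)
    V <- .signed_velocity(sw$wheels$R[al], phi, sw$mode, params)
    if (check_stall) {
      stall_count <<- if (any(V > 0)) 0L else stall_count + 1L
    }
    sw$wheels$x[al] <- pmax(0, x + V * config$dt)
    sw$t <- sw$t + config$dt
    sw
  }

  cs <- record(swarm)
  n_turns <- nrow(path$turns)
  for (ti in seq_len(n_turns)) {
    turn <- path$turns[ti, ]
    while (cs[["centroid"]] < turn$x) {
      if (swarm$t + config$dt > config$max_time + 1e-9) {
        termination <- "timed_out"; break
      }
      swarm <- step_forward(swarm, check_stall = TRUE)
      if (stall_count >= config$stall_steps) {
        termination <- "stalled"
        cs <- record(swarm)
        break
      }
      cs <- record(swarm)
    }
    if (!is.null(termination)) break
    swarm <- clip_at_turn(swarm, turn$x, turn$parallel_offsets[[1]],
                          sigma_keep = config$sigma_keep,
                          parallel_precedence = config$parallel_precedence,
                          label = turn$junction_id)
    if (!any(swarm$wheels$alive)) {
      termination <- "stalled"
      break
    }
    cs <- record(swarm)
  }

  if (is.null(termination)) {
    # collection: advance until the centroid moves collect_advance past its
    # post-final-turn position
    ref <- cs[["centroid"]]
    while (cs[["centroid"]] - ref < config$collect_advance) {
      if (swarm$t + config$dt > config$max_time + 1e-9) {
        termination <- "timed_out"; break
      }
      swarm <- step_forward(swarm, check_stall = FALSE)
      cs <- record(swarm)
    }
    if (is.null(termination)) termination <- "reached"
  }

  alive_mass <- sum(swarm$wheels$mass[swarm$wheels$alive])
  delivered <- if (termination == "reached") alive_mass else 0
  residual <- if (termination == "reached") 0 else alive_mass
  lost <- swarm$wheels[!swarm$wheels$alive, ]
  jl <- if (nrow(path$turns)) {
    data.frame(junction_id = path$turns$junction_id,
               lost_turn = vapply(path$turns$junction_id, function(id)
                 sum(lost$mass[lost$lost_to == paste0("turn:", id)]) / total,
                 0, USE.NAMES = FALSE),
               lost_parallel = vapply(path$turns$junction_id, function(id)
                 sum(lost$mass[lost$lost_to == paste0("parallel:", id)]) / total,
                 0, USE.NAMES = FALSE),
               row.names = NULL)
  } else {
    data.frame(junction_id = character(0), lost_turn = numeric(0),
               lost_parallel = numeric(0))
  }
  structure(list(
    efficiency = delivered / total,
    per_junction_losses = jl,
    residual = residual / total,
    termination = termination,
    trace = data.frame(t = trace_t, centroid = trace_c, sigma = trace_s,
                       alive_mass = trace_m),
    swarm = swarm),
    class = "uw_targeting_result")
}

#' @export
print.uw_targeting_result <- function(x, ...) {
  cat(sprintf("<uw_targeting_result> %s: efficiency %.1f%% after %d turns, t = %.1f s\n",
              x$termination, 100 * x$efficiency, nrow(x$per_junction_losses),
              max(x$trace$t)))
  invisible(x)
}
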