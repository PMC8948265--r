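test_that("Euler advance is exact on a flat constant-incline path", {
  net <- make_straight_net(c(0, 50), c(0, 0))
  path <- find_path(net)
  sw <- make_swarm(c(15e-6, 40e-6))
  V <- wheel_velocity(c(15e-6, 40e-6), 0, p_def)
  for (k in 1:25) sw <- advance_step(sw, net, path, p_def, dt = 0.1)
  expect_equal(sw$wheels$x, V * 25 * 0.1, tolerance = 1e-12)
  expect_equal(sw$t, 2.5)
})

test_that("advance matches an independent step-by-step re-integration", {
  # phi ramps 0 -> 60 mid-path; reference is a plain scalar loop
  net <- make_straight_net(c(0, 2, 4, 30), c(0, 0, 60, 60))
  path <- find_path(net)
  R <- 12e-6
  sw <- make_swarm(R)
  x_ref <- 0
  for (k in 1:300) {
    phi <- approx(path$knots$x, path$knots$phi_deg, xout = x_ref,
                  rule = 2)$y
    x_ref <- max(0, x_ref + wheel_velocity(R, phi, p_def) * 0.1)
    sw <- advance_step(sw, net, path, p_def, dt = 0.1)
    expect_equal(sw$wheels$x, x_ref, tolerance = 1e-12)
  }
})

test_that("dead wheels stay put and positions floor at the injection wall", {
  net <- make_straight_net(c(0, 50), c(80, 80))  # steep: big wheels slip back
  path <- find_path(net)
  sw <- make_swarm(c(60e-6, 10e-6))
  sw$wheels$alive[2] <- FALSE
  sw$wheels$x[2] <- 1e-3
  sw <- advance_step(sw, net, path, p_def, dt = 0.1)
  expect_equal(sw$wheels$x[1], 0)       # V < 0 but floored at the wall
  expect_equal(sw$wheels$x[2], 1e-3)    # dead wheel untouched
})

test_that("centroid and sigma are textbook weighted moments", {
  sw <- make_swarm(c(10e-6, 10e-6))
  sw$wheels$x <- c(1e-3, 3e-3)
  cs <- centroid_and_sigma(sw)
  expect_equal(cs[["centroid"]], 2e-3)
  expect_equal(cs[["sigma"]], 1e-3)
  one <- make_swarm(20e-6)
  expect_equal(centroid_and_sigma(one)[["sigma"]], 0)
  # random 100-wheel swarm against an independent computation
  sw <- gen_swarm("rolling", 100, params = p_def, seed = 21)
  sw$wheels$x <- runif(100, 0, 10e-3)
  m <- sw$wheels$mass; x <- sw$wheels$x
  xbar <- sum(m * x) / sum(m)
  sig <- sqrt(sum(m * (x - xbar)^2) / sum(m))
  cs <- centroid_and_sigma(sw)
  expect_equal(cs[["centroid"]], xbar, tolerance = 1e-12)
  expect_equal(cs[["sigma"]], sig, tolerance = 1e-12)
  sw$wheels$alive <- FALSE
  expect_error(centroid_and_sigma(sw), class = "uw_empty_swarm")
})

test_that("turn clipping applies both window rules as written", {
  sw <- make_swarm(rep(10e-6, 5))
  sw$wheels$x <- c(0.9, 1.0, 1.05, 1.3, 2.0) * 1e-3
  cs <- centroid_and_sigma(sw)
  turn_x <- 1.0e-3
  par_x <- 1.9e-3
  k <- 0.5
  # manual application of the rules
  keep <- abs(sw$wheels$x - turn_x) <= k * cs[["sigma"]]
  parhit <- abs(sw$wheels$x - par_x) <= k * cs[["sigma"]]
  clipped <- clip_at_turn(sw, turn_x, par_x, sigma_keep = k, label = "T")
  expect_identical(clipped$wheels$alive, keep & !parhit)
  expect_identical(clipped$wheels$lost_to[parhit & !keep][1], "parallel:T")
  expect_true(all(clipped$wheels$lost_to[!keep & !parhit] == "turn:T"))
  # no parallel offsets: only the keep-window rule fires
  clip2 <- clip_at_turn(sw, turn_x, numeric(0), sigma_keep = k)
  expect_identical(clip2$wheels$alive, keep)
  # sigma = 0: perfectly grouped swarm survives intact
  tight <- make_swarm(rep(10e-6, 3))
  tight$wheels$x <- rep(2e-3, 3)
  expect_true(all(clip_at_turn(tight, 2e-3)$wheels$alive))
})

test_that("parallel precedence flag controls the overlap case", {
  sw <- make_swarm(rep(10e-6, 4))
  sw$wheels$x <- c(0.5, 1.0, 1.1, 1.6) * 1e-3
  sig <- centroid_and_sigma(sw)[["sigma"]]
  # parallel mouth right at the turn: overlap wheels are in both windows
  a <- clip_at_turn(sw, 1.0e-3, 1.1e-3, sigma_keep = 0.5,
                    parallel_precedence = TRUE)
  b <- clip_at_turn(sw, 1.0e-3, 1.1e-3, sigma_keep = 0.5,
                    parallel_precedence = FALSE)
  expect_true(sum(a$wheels$alive) < sum(b$wheels$alive))
})

test_that("single wheel on a flat turnless path is fully delivered", {
  net <- make_straight_net(c(0, 10), c(0, 0))
  sw <- make_swarm(20e-6)
  res <- simulate_targeting(sw, net, params = p_def)
  expect_equal(res$efficiency, 1.0)
  expect_equal(res$termination, "reached")
  expect_equal(nrow(res$per_junction_losses), 0)
  expect_equal(res$residual, 0)
})

test_that("two-turn toy run matches an independent hand-rolled simulation", {
  net <- make_toy_net(par_mm = 6.5, target = "brB")
  path <- find_path(net)
  R <- seq(8e-6, 55e-6, length.out = 10)
  sw <- make_swarm(R)
  res <- simulate_targeting(sw, net, params = p_def)

  # reference: plain loop, no shared code beyond the velocity model
  m <- wheel_mass(R, p_def)
  V <- wheel_velocity(R, 0, p_def)   # toy net is flat everywhere
  x <- rep(0, 10); alive <- rep(TRUE, 10)
  wmean <- function(v, w) sum(v * w) / sum(w)
  losses <- c(0, 0)
  for (ti in 1:2) {
    turn_x <- path$turns$x[ti]
    repeat {
      x[alive] <- x[alive] + V[alive] * 0.1
      if (wmean(x[alive], m[alive]) >= turn_x) break
    }
    xb <- wmean(x[alive], m[alive])
    sg <- sqrt(wmean((x[alive] - xb)^2, m[alive]))
    keep <- abs(x - turn_x) <= 0.5 * sg
    par <- path$turns$parallel_offsets[[ti]]
    parhit <- if (length(par)) abs(x - par) <= 0.5 * sg else rep(FALSE, 10)
    newdead <- alive & !(keep & !parhit)
    losses[ti] <- sum(m[newdead])
    alive <- alive & keep & !parhit
  }
  expect_equal(res$efficiency, sum(m[alive]) / sum(m), tolerance = 1e-12)
  got <- res$per_junction_losses$lost_turn + res$per_junction_losses$lost_parallel
  expect_equal(unname(got), losses / sum(m), tolerance = 1e-12)
})

test_that("mass is conserved and the run is deterministic", {
  net <- gen_network(preset = "mca6")
  sw <- gen_swarm("rolling", 200, params = p_def, seed = 31)
  res1 <- simulate_targeting(sw, net, params = p_def)
  res2 <- simulate_targeting(sw, net, params = p_def)
  expect_identical(res1, res2)   # bit-identical: no hidden randomness
  book <- res1$efficiency + sum(res1$per_junction_losses$lost_turn) +
    sum(res1$per_junction_losses$lost_parallel) + res1$residual
  expect_equal(book, 1, tolerance = 1e-12)
  # alive-mass trace only decreases, and exactly by the recorded losses
  expect_true(all(diff(res1$trace$alive_mass) <= 1e-15))
  drop <- (res1$trace$alive_mass[1] -
             res1$trace$alive_mass[nrow(res1$trace)]) / sw$total_mass
  expect_equal(drop, sum(res1$per_junction_losses$lost_turn) +
                 sum(res1$per_junction_losses$lost_parallel),
               tolerance = 1e-12)
})

test_that("halving dt changes the toy-network efficiency by under 1%", {
  net <- make_toy_net(par_mm = 6.5, target = "brB")
  sw <- gen_swarm("rolling", 500, params = p_def, seed = 7)
  e1 <- simulate_targeting(sw, net, params = p_def,
                           config = sim_config(dt = 0.1))$efficiency
  e2 <- simulate_targeting(sw, net, params = p_def,
                           config = sim_config(dt = 0.05))$efficiency
  expect_lt(abs(e1 - e2), 0.01)
})

test_that("tightening the keep window never raises efficiency (no parallels)", {
  net <- gen_network(preset = "mca6")
  net$junctions$parallel_offsets <- replicate(nrow(net$junctions), numeric(0),
                                              simplify = FALSE)
  sw <- gen_swarm("rolling", 300, params = p_def, seed = 7)
  for (b in c("br1", "br2")) {
    net$target <- b
    effs <- vapply(c(0.25, 0.5, 1.0), function(k)
      simulate_targeting(sw, net, params = p_def,
                         config = sim_config(sigma_keep = k))$efficiency,
      numeric(1))
    expect_true(all(diff(effs) >= 0))
  }
})

test_that("an all-slip swarm stalls instead of looping forever", {
  # a steep trunk with one turn: stall detection runs in the pre-collection
  # (turn-seeking) phase
  mk <- function(id, branch, x_mm, kind, children = character(0)) {
    list(id = id, branch = branch, x = x_mm * 1e-3, phi_deg = 80, kind = kind,
         children = children, parallel_offsets = numeric(0))
  }
  rows <- list(mk("s", "trunk", 0, "waypoint"),
               mk("T1", "trunk", 15, "turn", c("brA", "brB")),
               mk("a1", "brA", 15, "waypoint"), mk("a2", "brA", 20, "terminal"),
               mk("b1", "brB", 15, "waypoint"), mk("b2", "brB", 21, "terminal"))
  j <- data.frame(id = vapply(rows, `[[`, "", "id"),
                  branch = vapply(rows, `[[`, "", "branch"),
                  x = vapply(rows, `[[`, 0, "x"),
                  phi_deg = vapply(rows, `[[`, 0, "phi_deg"),
                  kind = vapply(rows, `[[`, "", "kind"),
                  stringsAsFactors = FALSE)
  j$children <- lapply(rows, `[[`, "children")
  j$parallel_offsets <- lapply(rows, `[[`, "parallel_offsets")
  net <- uw_network(j, target = "brA")
  sw <- make_swarm(c(55e-6, 60e-6))  # only slipping wheels at 80 degrees
  res <- simulate_targeting(sw, net, params = p_def)
  expect_equal(res$termination, "stalled")
  expect_equal(res$efficiency, 0)
  expect_equal(res$residual, 1)
})

test_that("a too-short clock times out", {
  net <- make_straight_net(c(0, 100), c(0, 0))
  sw <- make_swarm(10e-6)
  res <- simulate_targeting(sw, net, params = p_def,
                            config = sim_config(max_time = 5))
  expect_equal(res$termination, "timed_out")
  expect_lte(max(res$trace$t), 5 + 1e-9)
})
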