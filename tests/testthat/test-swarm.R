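test_that("wheel mass follows the bead-count law", {
  p <- p_def
  a <- p$bead$a
  expect_equal(wheel_mass(a, p), bead_mass(p))            # R = a -> one bead
  expect_equal(wheel_mass(2 * a, p) / wheel_mass(a, p), 4)  # n ~ R^2
  # HCP option: ratio equals the 2D close-packing density, computed
  # independently from circle geometry: one unit circle per hexagonal cell
  # of inradius 1 (side 2/sqrt(3))
  hex_area <- 6 * (sqrt(3) / 4) * (2 / sqrt(3))^2
  hex_density <- pi / hex_area
  expect_equal(wheel_mass(10e-6, p, packing = "hcp") / wheel_mass(10e-6, p),
               hex_density, tolerance = 1e-12)
  expect_error(wheel_mass(1e-6, p), class = "uw_invalid_radius")
})

test_that("mode radius laws respect the printed truncation bounds", {
  expect_error(swarm_mode("flipping", dist = list(lower_um = 2)),
               class = "uw_domain_error")
  expect_error(swarm_mode("rolling", switchback_angle = 35),
               class = "uw_domain_error")
  sw <- gen_swarm("flipping", 1000, params = p_def, seed = 3)
  expect_true(all(sw$wheels$R >= 4.5e-6 & sw$wheels$R <= 20e-6))
  sw <- gen_swarm("rolling", 1000, params = p_def, seed = 3)
  expect_true(all(sw$wheels$R >= 4.5e-6 & sw$wheels$R <= 60e-6))
})

test_that("sampled radii match the truncated law's analytic mean", {
  n <- 5000
  sw <- gen_swarm("rolling", n, params = p_def, seed = 17)
  d <- sw$mode$dist
  # independent oracle: numerical integration of the truncated density
  Z <- integrate(dlnorm, d$lower_um, d$upper_um, meanlog = d$meanlog,
                 sdlog = d$sdlog)$value
  mu <- integrate(function(x) x * dlnorm(x, d$meanlog, d$sdlog) / Z,
                  d$lower_um, d$upper_um)$value
  s2 <- integrate(function(x) (x - mu)^2 * dlnorm(x, d$meanlog, d$sdlog) / Z,
                  d$lower_um, d$upper_um)$value
  se <- sqrt(s2 / n)
  expect_lt(abs(mean(sw$wheels$R) * 1e6 - mu), 3 * se)
})

test_that("mass profiles conserve mass and start as a point mass", {
  sw <- gen_swarm("rolling", 300, params = p_def, seed = 5)
  prof0 <- predict_mass_profile(sw, 0, phi = 0, params = p_def)
  expect_equal(sum(prof0$mass_fraction), 1, tolerance = 1e-12)
  expect_equal(max(prof0$mass_fraction), 1, tolerance = 1e-12)  # single bin
  prof <- predict_mass_profile(sw, 20, phi = 0, params = p_def)
  expect_equal(sum(prof$mass_fraction), 1, tolerance = 1e-12)
  # the area under every mode's curve is equal at fixed t
  for (m in c("switchback", "flipping", "corkscrew")) {
    swm <- gen_swarm(m, 300, params = p_def, seed = 5)
    pm <- predict_mass_profile(swm, 20, phi = 0, params = p_def)
    expect_equal(sum(pm$mass_fraction), sum(prof$mass_fraction),
                 tolerance = 1e-12)
  }
})

test_that("two-wheel profile puts each wheel's mass at v_i * t", {
  sw <- make_swarm(c(10e-6, 50e-6))
  t <- 30
  V <- wheel_velocity(c(10e-6, 50e-6), 0, p_def)
  prof <- predict_mass_profile(sw, t, phi = 0, params = p_def, breaks = 40)
  idx <- findInterval(V * t, prof$bin_edges, rightmost.closed = TRUE)
  masses <- sw$wheels$mass / sw$total_mass
  expect_equal(prof$mass_fraction[idx], masses, tolerance = 1e-12)
  expect_equal(sum(prof$mass_fraction > 0), 2)
})

test_that("positional spread grows with time for heterogeneous swarms", {
  sw <- gen_swarm("rolling", 400, params = p_def, seed = 9)
  sigma_at <- function(t) {
    x <- mode_velocity(sw$wheels$R, 0, sw$mode, p_def) * t
    m <- sw$wheels$mass
    xb <- sum(m * x) / sum(m)
    sqrt(sum(m * (x - xb)^2) / sum(m))
  }
  s <- vapply(c(0, 5, 20, 60, 120), sigma_at, numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("centroid velocity is the mass-weighted mean of wheel velocities", {
  one <- make_swarm(25e-6)
  expect_equal(centroid_velocity(one, 30, p_def),
               wheel_velocity(25e-6, 30, p_def))
  # two wheels with equal mass -> arithmetic mean
  R2 <- c(20e-6, 20e-6)
  two <- make_swarm(R2)
  expect_equal(centroid_velocity(two, 10, p_def),
               mean(wheel_velocity(R2, 10, p_def)))
  dead <- make_swarm(10e-6)
  dead$wheels$alive <- FALSE
  expect_error(centroid_velocity(dead, 0, p_def), class = "uw_empty_swarm")
})

test_that("mode kinematics: switchback climbs where rolling slips", {
  roll <- gen_swarm("rolling", 400, params = p_def, seed = 13)
  swb <- gen_swarm("switchback", 400, params = p_def, seed = 13)
  expect_gt(centroid_velocity(swb, 80, p_def),
            centroid_velocity(roll, 80, p_def))
  expect_lt(centroid_velocity(roll, 80, p_def), 0)  # rolling slips back
  # larger component wheels -> faster swarm on the flat
  flip <- gen_swarm("flipping", 400, params = p_def, seed = 13)
  cork <- gen_swarm("corkscrew", 400, params = p_def, seed = 13)
  cv0 <- function(s) centroid_velocity(s, 0, p_def)
  expect_gt(cv0(roll), cv0(cork))
  expect_gt(cv0(cork), cv0(flip))
  expect_gt(cv0(roll), cv0(swb))
})

test_that("swarm CSV round-trips", {
  sw <- gen_swarm("corkscrew", 50, params = p_def, seed = 2)
  sw$wheels$x <- runif(50, 0, 5e-3)
  sw$wheels$alive[1:5] <- FALSE
  path <- withr::local_tempfile(fileext = ".csv")
  write_swarm_csv(sw, path)
  back <- read_swarm_csv(path, mode = sw$mode, params = p_def)
  expect_equal(back$wheels$R, sw$wheels$R, tolerance = 1e-12)
  expect_equal(back$wheels$mass, sw$wheels$mass, tolerance = 1e-12)
  expect_equal(back$wheels$x, sw$wheels$x, tolerance = 1e-12)
  expect_identical(back$wheels$alive, sw$wheels$alive)
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", path2)
  expect_error(read_swarm_csv(path2), class = "uw_format_error")
})
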