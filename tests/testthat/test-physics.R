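test_that("rotation rate scales as 1/R and matches the torque-balance oracle", {
  p <- p_def
  # with n = (R/a)^2 the 1/R cancellation makes omega(2R)/omega(R) = 1/2
  expect_equal(rotation_rate(20e-6, p) / rotation_rate(10e-6, p), 0.5)
  # log-log slope -1 across the full 5-70 um range
  R <- seq(5e-6, 70e-6, length.out = 25)
  slope <- coef(lm(log(rotation_rate(R, p)) ~ log(R)))[[2]]
  expect_equal(slope, -1, tolerance = 1e-10)
  # torque-balance route equals an independent term-by-term evaluation
  p2 <- p
  p2$field$c_omega <- NULL
  p2$bead$chi_imag <- 0.03
  for (R1 in c(6e-6, 22e-6, 55e-6))
    expect_equal(rotation_rate(R1, p2),
                 oracle_omega(R1, p$bead$a, p$fluid$eta, p$field$B, 0.03),
                 tolerance = 1e-12)
  expect_error(rotation_rate(1e-6, p), class = "uw_invalid_radius")
})

test_that("gap-width closed form (k1 = 1) equals the root of the normal balance", {
  for (R in c(5e-6, 20e-6, 70e-6))
    for (phi in c(0, 30, 80))
      expect_equal(gap_width(R, phi, p_def, k1 = 1), oracle_gap(R, phi, p_def),
                   tolerance = 1e-10)
})

test_that("gap width grows with incline and shrinks with load", {
  # cos(phi) lowers the load, widening the gap
  expect_lt(gap_width(10e-6, 0, p_def), gap_width(10e-6, 60, p_def))
  # monotone decreasing in normal load W_y across the (R, phi) surface
  grid <- expand.grid(R = seq(5e-6, 70e-6, length.out = 12),
                      phi = seq(0, 80, by = 10))
  Wy <- bead_mass(p_def) * 9.80665 * (grid$R / p_def$bead$a)^2 *
    cos(grid$phi * pi / 180)
  delta <- gap_width(grid$R, grid$phi, p_def)
  ord <- order(Wy)
  expect_true(all(diff(delta[ord]) < 0))
})

test_that("pinned wheels raise a distinct error", {
  p <- p_def
  p$fluid$zeta_particle <- 1e-4  # repulsion too weak to carry the load
  expect_error(gap_width(60e-6, 0, p), class = "uw_pinned_error")
  expect_error(gap_width(60e-6, 0, p), "pinned")
  expect_error(wheel_velocity(60e-6, 0, p), class = "uw_pinned_error")
})

test_that("closed-form velocity equals the force-balance root over the grid", {
  grid <- expand.grid(R = seq(5e-6, 70e-6, length.out = 20),
                      phi = seq(0, 80, by = 10))
  V <- wheel_velocity(grid$R, grid$phi, p_def)
  V_root <- mapply(oracle_velocity, grid$R, grid$phi, MoreArgs = list(p_def))
  expect_equal(V, V_root, tolerance = 1e-8)
})

test_that("velocity regimes: rolling with slip, never faster than omega R", {
  p <- p_def
  R <- seq(5e-6, 70e-6, length.out = 20)
  for (phi in c(0, 40, 80)) {
    V <- wheel_velocity(R, phi, p)
    expect_true(all(V < rotation_rate(R, p) * R))  # always slipping
  }
  expect_true(all(wheel_velocity(R, 0, p) > 0))    # all climb on the flat
  # V strictly decreasing in phi at fixed R
  for (R1 in c(8e-6, 30e-6, 65e-6))
    expect_true(all(diff(wheel_velocity(R1, seq(0, 80, by = 5), p)) < 0))
  # large wheels slip backwards at 80 deg; small ones do not
  expect_lt(wheel_velocity(60e-6, 80, p), 0)
  expect_gt(wheel_velocity(10e-6, 80, p), 0)
  # percent drop flat -> 80 deg is smaller for small wheels
  drop <- function(R1) {
    v0 <- wheel_velocity(R1, 0, p)
    (v0 - wheel_velocity(R1, 80, p)) / v0
  }
  expect_lt(drop(10e-6), drop(60e-6))
})

test_that("effective incline lowers the climbing angle as expected", {
  expect_equal(effective_incline(80, 35), 53.8, tolerance = 0.01)
  expect_equal(effective_incline(40, 0), 40)
  expect_equal(effective_incline(0, 60), 0)
  phis <- seq(5, 90, by = 5)
  expect_true(all(effective_incline(phis, 35) < phis))
  expect_error(effective_incline(100, 35), class = "uw_domain_error")
  expect_error(effective_incline(40, 95), class = "uw_domain_error")
})

test_that("dimensionless groups are mutually consistent", {
  p <- p_def
  d1 <- dimensionless_groups(p, gamma_dot = 10)
  d2 <- dimensionless_groups(p, gamma_dot = 20)
  expect_equal(d2$Mn / d1$Mn, 2)                       # linear in shear rate
  expect_equal(d1$Mn, d1$Pe / d1$lam, tolerance = 1e-12)
  # rim estimate: with omega ~ 1/R, Mn is independent of wheel size
  R <- c(5e-6, 20e-6, 60e-6)
  Mn <- dimensionless_groups(p, omega = rotation_rate(R, p), R = R, l = 5e-6)$Mn
  expect_equal(max(Mn) / min(Mn), 1, tolerance = 1e-12)
  expect_error(dimensionless_groups(p, omega = 10), class = "uw_domain_error")
})

test_that("force breakdown balances at the solved velocity", {
  for (R in c(8e-6, 35e-6, 65e-6)) {
    for (phi in c(0, 50, 80)) {
      fb <- force_breakdown(R, phi, p_def)
      expect_lt(abs(fb$residual),
                1e-12 * max(abs(fb$F_f), abs(fb$F_d), abs(fb$W_x)))
      expect_equal(fb$mu_k, fb$F_f / fb$W_y)  # Eq.-consistency of mu_k
      expect_equal(fb$F_es, fb$W_y)           # normal balance at solved gap
      expect_equal(fb$W_y, fb$W_total * cos(phi * pi / 180))
    }
  }
  expect_equal(force_breakdown(20e-6, 0, p_def)$W_x, 0)
})
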