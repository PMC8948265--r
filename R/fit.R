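#' Refit the shape factors k1 and k2 from (R, phi, V) data
#'
#' Nonlinear least squares on the closed-form incline velocity model: finds
#' the `(k1, k2)` minimizing the sum of squared velocity residuals over a
#' table of observed radius/incline/velocity triples. Optimization is in log
#' space (both factors are positive) with Nelder-Mead followed by a BFGS
#' polish.
#'
#' @param data A data.frame with columns `R` (m), `phi` (deg) and `V` (m/s).
#' @param params A `uw_params` object supplying every non-fitted physical
#'   parameter; its `fit` slot is ignored.
#' @param start Numeric length-2 vector of starting values `c(k1, k2)`.
#' @return A list with `k1`, `k2`, `rss` (residual sum of squares) and
#'   `convergence` (0 = success, from [stats::optim()]).
#' @examples
#' p <- default_params()
#' d <- gen_velocity_data(params = p, noise_sd = 0, seed = 1)
#' fit_friction_params(d, p)  # recovers k1 = 1.50, k2 = 3.11
#' @export
fit_friction_params <- function(data, params, start = c(k1 = 1, k2 = 1)) {
  uw_check(all(c("R", "phi", "V") %in% names(data)),
           "data must have columns R, phi, V")
  uw_check(all(start > 0), "start values must be positive")
  obj <- function(logk) {
    p <- params
    p$fit <- fit_params(k1 = exp(logk[[1]]), k2 = exp(logk[[2]]))
    sum((wheel_velocity(data$R, data$phi, p) - data$V)^2)
  }
  fit <- stats::optim(log(start), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  list(k1 = exp(fit$par[[1]]), k2 = exp(fit$par[[2]]),
       rss = fit$value, convergence = fit$convergence)
}

#' Generate a synthetic (R, phi, V) velocity table
#'
#' Evaluates the full incline model on a regular grid of `n_R` radii spanning
#' 5-70 um and `n_phi` incline angles spanning 0-80 degrees (200 points by
#' default) and applies multiplicative Gaussian noise `V * (1 + e)`,
#' `e ~ N(0, noise_sd)`. This is the fixture for the k1/k2 recovery
#' experiment.
#'
#' @param params A `uw_params` object (its `fit` slot provides the true
#'   `k1`, `k2`).
#' @param n_R,n_phi Grid sizes. Defaults 20 and 10.
#' @param R_range Radius range (m). Default 5-70 um.
#' @param phi_range Incline range (deg). Default 0-80.
#' @param noise_sd Multiplicative noise standard deviation. Default 0.02.
#' @param seed Optional RNG seed for the noise draw.
#' @return A data.frame with columns `R`, `phi`, `V` (noisy) and `V_true`.
#' @export
gen_velocity_data <- function(params = default_params(), n_R = 20, n_phi = 10,
                              R_range = c(5e-6, 70e-6), phi_range = c(0, 80),
                              noise_sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(R = seq(R_range[1], R_range[2], length.out = n_R),
                      phi = seq(phi_range[1], phi_range[2], length.out = n_phi))
  V_true <- wheel_velocity(grid$R, grid$phi, params)
  eps <- if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
  data.frame(R = grid$R, phi = grid$phi, V = V_true * (1 + eps),
             V_true = V_true)
}
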