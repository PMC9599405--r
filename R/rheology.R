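#' Ostwald-de Waele power-law parameters
#'
#' Constitutive parameters of the power-law (Ostwald-de Waele) model
#' \eqn{\tau = k \dot\gamma^n} used for shear-thinning hydrogel inks.
#'
#' @param k Flow consistency index, Pa s^n. Must be positive.
#' @param n Flow behavior index (dimensionless). Must satisfy `0 < n <= 2`;
#'   `n < 1` is shear thinning, `n = 1` Newtonian.
#' @param fit_range Numeric length-2 vector `(gamma_min, gamma_max)` in 1/s,
#'   the shear-rate window over which the parameters are valid / were fitted.
#'
#' @return An object of class `power_law_params`.
#' @examples
#' silk <- power_law_params(k = 148.89, n = 0.2025)
#' shear_stress(silk, 1)    # equals k at unit shear rate
#' @export
power_law_params <- function(k, n, fit_range = c(0.1, 10)) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(fit_range), length(fit_range) == 2L)
  if (k <= 0) stop("flow consistency index k must be positive")
  if (n <= 0 || n > 2) stop("flow behavior index n must lie in (0, 2]")
  if (!(fit_range[1] > 0 && fit_range[1] < fit_range[2]))
    stop("fit_range must satisfy 0 < gamma_min < gamma_max")
  structure(list(k = k, n = n, fit_range = as.numeric(fit_range)),
            class = "power_law_params")
}

#' @export
print.power_law_params <- function(x, ...) {
  cat(sprintf("Power-law fluid: k = %.6g Pa*s^n, n = %.6g  (valid %.3g-%.3g 1/s)\n",
              x$k, x$n, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Flow curve container
#'
#' A measured (or synthetic) steady-shear flow curve: shear stress versus
#' shear rate.
#'
#' @param shear_rate Strictly increasing, strictly positive shear rates, 1/s.
#' @param shear_stress Strictly positive shear stresses, Pa; same length.
#' @return A `flow_curve` data frame with columns `shear_rate` and
#'   `shear_stress`.
#' @export
flow_curve <- function(shear_rate, shear_stress) {
  stopifnot(is.numeric(shear_rate), is.numeric(shear_stress))
  if (length(shear_rate) != length(shear_stress))
    stop("shear_rate and shear_stress must have equal length")
  if (length(shear_rate) < 3L) stop("a flow curve needs at least 3 points")
  if (any(shear_rate <= 0) || any(shear_stress <= 0))
    stop("flow-curve entries must be strictly positive")
  if (any(diff(shear_rate) <= 0))
    stop("shear_rate must be strictly increasing")
  structure(data.frame(shear_rate = shear_rate, shear_stress = shear_stress),
            class = c("flow_curve", "data.frame"))
}

#' Shear stress of a power-law fluid
#'
#' Evaluates \eqn{\tau = k \dot\gamma^n}.
#'
#' @param params A [power_law_params] object.
#' @param gamma_dot Shear rate(s), 1/s; strictly positive.
#' @return Shear stress in Pa, same length as `gamma_dot`.
#' @export
shear_stress <- function(params, gamma_dot) {
  stopifnot(inherits(params, "power_law_params"), is.numeric(gamma_dot))
  if (any(gamma_dot <= 0)) stop("gamma_dot must be strictly positive")
  params$k * gamma_dot^params$n
}

#' Apparent viscosity of a power-law fluid
#'
#' \eqn{\eta(\dot\gamma) = k \dot\gamma^{n-1}}; strictly decreasing in
#' shear rate when `n < 1` (shear thinning).
#'
#' @inheritParams shear_stress
#' @return Apparent viscosity in Pa s.
#' @export
apparent_viscosity <- function(params, gamma_dot) {
  shear_stress(params, gamma_dot) / gamma_dot
}

#' Fit power-law parameters to a flow curve
#'
#' Ordinary least squares in (log shear rate, log shear stress) space,
#' restricted to `fit_range`: the slope is the flow behavior index `n`, the
#' intercept is `log(k)`. On noiseless power-law data the recovery is exact to
#' numerical precision. Points outside the range are excluded (their count is
#' reported in the result); the fitter reports the raw slope and validation in
#' [power_law_params] flags out-of-range results.
#'
#' @param curve A [flow_curve].
#' @param fit_range Shear-rate window `(gamma_min, gamma_max)` in 1/s.
#' @return A [power_law_params] with attributes `n_points_used` and
#'   `n_points_excluded`.
#' @export
fit_power_law <- function(curve, fit_range = c(0.1, 10)) {
  stopifnot(inherits(curve, "flow_curve") || is.data.frame(curve))
  gd <- curve$shear_rate
  tau <- curve$shear_stress
  if (any(gd <= 0) || any(tau <= 0))
    stop("flow-curve entries must be strictly positive")
  keep <- gd >= fit_range[1] * (1 - 1e-9) & gd <= fit_range[2] * (1 + 1e-9)
  if (sum(keep) < 3L)
    stop("insufficient data: fewer than 3 points inside the fit range")
  fit <- stats::lm.fit(cbind(1, log(gd[keep])), log(tau[keep]))
  k_hat <- exp(fit$coefficients[[1]])
  n_hat <- fit$coefficients[[2]]
  out <- power_law_params(k = k_hat, n = n_hat, fit_range = fit_range)
  attr(out, "n_points_used") <- sum(keep)
  attr(out, "n_points_excluded") <- sum(!keep)
  out
}

#' Metzner-Reed generalized Reynolds number
#'
#' Generalized Reynolds number for power-law pipe flow,
#' \deqn{Re = \frac{\rho U^{2-n} D^n}{k\,((3n+1)/(4n))^n\,8^{n-1}},}
#' reducing to the classic \eqn{\rho U D / k} for `n = 1`. Values far below
#' 2100 support the laminar / creeping-flow assumption of the cartridge model.
#'
#' @param params A [power_law_params].
#' @param density Fluid density, kg/m^3.
#' @param mean_velocity Cross-section mean velocity, m/s.
#' @param diameter Tube diameter, m.
#' @return Dimensionless Reynolds number.
#' @export
metzner_reed_reynolds <- function(params, density, mean_velocity, diameter) {
  stopifnot(is.numeric(density), is.numeric(mean_velocity), is.numeric(diameter))
  if (any(c(density, mean_velocity, diameter) <= 0))
    stop("density, mean_velocity and diameter must be positive")
  n <- params$n
  k <- params$k
  density * mean_velocity^(2 - n) * diameter^n /
    (k * ((3 * n + 1) / (4 * n))^n * 8^(n - 1))
}
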