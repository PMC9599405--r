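#' Synthetic power-law flow curve
#'
#' Generates a steady-shear flow curve from the power-law model with
#' multiplicative log-normal noise,
#' \eqn{\tau_i = k\dot\gamma_i^n \exp(\varepsilon_i)},
#' \eqn{\varepsilon_i \sim N(0, \sigma^2)}, at log-spaced shear rates. Noise is
#' multiplicative so synthetic stresses stay strictly positive. A fixed seed
#' makes the output bit-identical across runs; `sigma = 0` returns the exact
#' model curve.
#'
#' @param params True [power_law_params] (defaults: the fitted spider-silk
#'   hydrogel values k = 148.89 Pa s^n, n = 0.2025 over 0.1-10 1/s).
#' @param n_points Number of log-spaced shear rates over the fit range.
#' @param sigma Log-scale noise standard deviation (default 0.05, i.e. ~5% of
#'   signal).
#' @param seed RNG seed; mandatory when `sigma > 0`.
#' @return A [flow_curve].
#' @export
synth_flow_curve <- function(params = power_law_params(148.89, 0.2025),
                             n_points = 50L, sigma = 0.05, seed = NULL) {
  stopifnot(sigma >= 0, n_points >= 3L)
  if (sigma > 0 && is.null(seed))
    stop("a seed is mandatory for stochastic synthetic output")
  gd <- exp(seq(log(params$fit_range[1]), log(params$fit_range[2]),
                length.out = n_points))
  tau <- shear_stress(params, gd)
  if (sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    tau <- tau * exp(stats::rnorm(n_points, 0, sigma))
  }
  flow_curve(gd, tau)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic replicated strand fluorescence samples
#'
#' Emulates equal-distance sampling of a printed strand followed by
#' fluorometry: hydrogel is sampled every `interval` metres starting at 0,
#' each position measured with `n1` technical replicates on each of `n2`
#' scaffolds, the measured intensity being the inner-filter response of the
#' local labeled fraction plus additive Gaussian instrument noise (standard
#' deviation `sigma` times the maximum noiseless response).
#'
#' @param strand A [strand_profile] of labeled fraction (`C_A` interpreted as
#'   the labeled-material fraction at each position).
#' @param interval Sampling spacing, m (default 0.03, i.e. 3 cm).
#' @param n1 Technical replicates per spot (default 3).
#' @param n2 Scaffold replicates (default 3).
#' @param ifp An [inner_filter_params].
#' @param sigma Relative additive noise level (default 0.05).
#' @param seed RNG seed; mandatory when `sigma > 0`.
#' @return Data frame with columns `s_m`, `scaffold`, `replicate`, `C_true`,
#'   `intensity`; `n1 * n2` rows per position.
#' @export
synth_strand_samples <- function(strand, interval = 0.03, n1 = 3L, n2 = 3L,
                                 ifp = inner_filter_params(),
                                 sigma = 0.05, seed = NULL) {
  stopifnot(is.data.frame(strand), sigma >= 0, n1 >= 1L, n2 >= 1L,
            interval > 0)
  if (sigma > 0 && is.null(seed))
    stop("a seed is mandatory for stochastic synthetic output")
  s_max <- max(strand$s_m)
  if (interval > s_max)
    stop("insufficient strand length: sampling interval exceeds the strand")
  pos <- seq(0, s_max, by = interval)
  C <- stats::approx(strand$s_m, strand$C_A, xout = pos, rule = 2)$y
  C <- pmin(pmax(C, 0), 1)
  base <- fluorescence_response(C, ifp)
  grid <- expand.grid(replicate = seq_len(n1), scaffold = seq_len(n2),
                      idx = seq_along(pos))
  out <- data.frame(s_m = pos[grid$idx],
                    scaffold = grid$scaffold,
                    replicate = grid$replicate,
                    C_true = C[grid$idx],
                    intensity = base[grid$idx])
  if (sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    out$intensity <- out$intensity +
      stats::rnorm(nrow(out), 0, sigma * max(base))
  }
  out[order(out$s_m, out$scaffold, out$replicate), , drop = FALSE]
}

#' Reference run configuration
#'
#' The default parameter set used throughout the package: the fitted
#' spider-silk hydrogel power law (k = 148.89 Pa s^n, n = 0.2025, valid
#' 0.1-10 1/s), a 3cc cartridge with a 20G conical needle, 5 mm/s piston
#' speed, 0.1 s reporting step, 20 mm/s print speed, and a 1:2 AB block fill
#' (10 mm A / 20 mm B, ~0.7 and ~1.5 mL).
#'
#' @param wall_mode `"no_slip"` (default) or `"slip"`.
#' @return Named list with elements `params`, `geom`, `fill`, `settings`.
#' @export
default_run_config <- function(wall_mode = c("no_slip", "slip")) {
  wall_mode <- match.arg(wall_mode)
  geom <- cartridge_geometry(needle_gauge = 20)
  list(params = power_law_params(148.89, 0.2025, c(0.1, 10)),
       geom = geom,
       fill = block_fill(10e-3, 20e-3, geom),
       settings = extrusion_settings(piston_speed = 5e-3, time_step = 0.1,
                                     wall_mode = wall_mode,
                                     print_speed = 20e-3))
}
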