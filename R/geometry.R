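#' Needle gauge to inner diameter presets
#'
#' Industry-convention inner diameters for conical Luer-lock printing needles.
#'
#' @param gauge Integer gauge: one of 14, 16, 20.
#' @return Inner diameter in metres.
#' @export
gauge_inner_diameter <- function(gauge) {
  tab <- c(`14` = 1.60e-3, `16` = 1.19e-3, `20` = 0.603e-3)
  key <- as.character(gauge)
  if (!key %in% names(tab))
    stop("unknown needle gauge; presets exist for 14, 16, 20")
  unname(tab[key])
}

#' Axisymmetric cartridge geometry
#'
#' Straight barrel of radius `barrel_radius` and length `barrel_length`,
#' followed by a linear conical taper of length `cone_length` down to
#' `outlet_radius`. Defaults are conventional 3cc-cartridge dimensions with a
#' 20G needle preset.
#'
#' @param barrel_radius Barrel inner radius, m.
#' @param barrel_length Straight barrel length, m.
#' @param cone_length Conical tip length, m.
#' @param outlet_radius Outlet radius, m. Ignored when `needle_gauge` is given.
#' @param needle_gauge Optional needle gauge (14, 16 or 20) setting the outlet
#'   radius from the preset table.
#' @return A `cartridge_geometry` object.
#' @export
cartridge_geometry <- function(barrel_radius = 4.8e-3,
                               barrel_length = 55e-3,
                               cone_length = 8e-3,
                               outlet_radius = NULL,
                               needle_gauge = NULL) {
  if (!is.null(needle_gauge)) outlet_radius <- gauge_inner_diameter(needle_gauge) / 2
  if (is.null(outlet_radius)) outlet_radius <- gauge_inner_diameter(20) / 2
  stopifnot(barrel_radius > 0, barrel_length > 0, cone_length > 0)
  if (!(outlet_radius > 0 && outlet_radius < barrel_radius))
    stop("outlet_radius must satisfy 0 < R_o < R_b")
  structure(list(barrel_radius = barrel_radius,
                 barrel_length = barrel_length,
                 cone_length = cone_length,
                 outlet_radius = outlet_radius),
            class = "cartridge_geometry")
}

#' @export
print.cartridge_geometry <- function(x, ...) {
  cat(sprintf(
    "Cartridge: R_b = %.3g mm, L_bar = %.3g mm, cone %.3g mm -> R_o = %.3g mm\n",
    1e3 * x$barrel_radius, 1e3 * x$barrel_length,
    1e3 * x$cone_length, 1e3 * x$outlet_radius))
  invisible(x)
}

#' Local cartridge radius R(z)
#'
#' Piecewise-linear radius profile: constant in the barrel, linear taper in
#' the cone. `z = 0` is the barrel entrance (fully retracted piston); the
#' outlet plane is at `barrel_length + cone_length`.
#'
#' @param geom A [cartridge_geometry].
#' @param z Axial position(s), m.
#' @return Radius in m.
#' @export
local_radius <- function(geom, z) {
  zc <- geom$barrel_length
  ze <- geom$barrel_length + geom$cone_length
  if (any(z < 0 | z > ze + 1e-12)) stop("z outside the cartridge domain")
  ifelse(z <= zc,
         geom$barrel_radius,
         geom$barrel_radius + (geom$outlet_radius - geom$barrel_radius) *
           (pmin(z, ze) - zc) / geom$cone_length)
}

#' AB block fill
#'
#' Initial axial extents of the two material blocks: A on the outlet side,
#' B on the piston side, with a flat contact interface.
#'
#' @param block_A Axial length of block A (outlet side), m.
#' @param block_B Axial length of block B (piston side), m.
#' @param geom Optional [cartridge_geometry] used to check that the fill fits
#'   in the barrel.
#' @return A `block_fill` object.
#' @export
block_fill <- function(block_A = 10e-3, block_B = 20e-3, geom = NULL) {
  stopifnot(block_A > 0, block_B > 0)
  if (!is.null(geom) && block_A + block_B > geom$barrel_length + 1e-12)
    stop("fill does not fit: block_A + block_B exceeds the barrel length")
  structure(list(block_A = block_A, block_B = block_B), class = "block_fill")
}

#' Extrusion settings
#'
#' @param piston_speed Piston crown speed v, m/s (paper setting: 5 mm/s).
#' @param time_step Output/reporting time step, s (paper setting: 0.1 s).
#' @param wall_mode `"slip"` (free-slip walls, plug flow) or `"no_slip"`
#'   (zero wall velocity, U-shaped power-law profile).
#' @param print_speed Print-head travel speed, m/s (paper setting: 20 mm/s).
#' @param pneumatic_pressure Stored as run metadata only (Pa); the engine is
#'   velocity driven.
#' @return An `extrusion_settings` object.
#' @export
extrusion_settings <- function(piston_speed = 5e-3,
                               time_step = 0.1,
                               wall_mode = c("no_slip", "slip"),
                               print_speed = 20e-3,
                               pneumatic_pressure = 1e4) {
  wall_mode <- match.arg(wall_mode)
  stopifnot(piston_speed > 0, time_step > 0, print_speed > 0)
  structure(list(piston_speed = piston_speed, time_step = time_step,
                 wall_mode = wall_mode, print_speed = print_speed,
                 pneumatic_pressure = pneumatic_pressure),
            class = "extrusion_settings")
}

#' Normalized axial velocity profile
#'
#' Dimensionless multiplier \eqn{\phi(\xi)} of the cross-section mean velocity
#' at normalized radius \eqn{\xi = r/R}. Free slip gives a plug
#' (\eqn{\phi \equiv 1}); no slip gives the fully developed power-law tube
#' profile
#' \deqn{\phi(\xi) = \frac{3n+1}{n+1}\left(1 - \xi^{(n+1)/n}\right),}
#' whose flux-weighted mean \eqn{2\int_0^1 \phi\,\xi\,d\xi} is 1 in both modes.
#'
#' @param xi Normalized radius in `[0, 1]`.
#' @param n Flow behavior index.
#' @param wall_mode `"slip"` or `"no_slip"`.
#' @return Velocity multiplier, same length as `xi`.
#' @export
profile_shape <- function(xi, n, wall_mode = c("no_slip", "slip")) {
  wall_mode <- match.arg(wall_mode)
  stopifnot(n > 0)
  if (any(xi < 0 | xi > 1)) stop("xi must lie in [0, 1]")
  if (wall_mode == "slip") return(rep(1, length(xi)))
  m <- (n + 1) / n
  ((3 * n + 1) / (n + 1)) * (1 - xi^m)
}

#' Cumulative flux fraction of the velocity profile
#'
#' \eqn{F(\xi) = 2\int_0^\xi \phi(s)\,s\,ds}, the fraction of the volumetric
#' flow carried inside normalized radius `xi`. `F(0) = 0`, `F(1) = 1`. Closed
#' form for both wall modes.
#'
#' @inheritParams profile_shape
#' @return Flux fraction in `[0, 1]`.
#' @export
flux_fraction <- function(xi, n, wall_mode = c("no_slip", "slip")) {
  wall_mode <- match.arg(wall_mode)
  stopifnot(n > 0)
  if (any(xi < 0 | xi > 1)) stop("xi must lie in [0, 1]")
  if (wall_mode == "slip") return(xi^2)
  m <- (n + 1) / n
  cpre <- (3 * n + 1) / (n + 1)
  cpre * (xi^2 - 2 * xi^(m + 2) / (m + 2))
}

#' Inverse of the cumulative flux fraction
#'
#' Returns `xi` such that [flux_fraction] equals `q`. Monotone spline lookup
#' refined by Newton iterations; used to seed interface markers on an
#' equal-flux radial grid.
#'
#' @param q Flux fraction(s) in `[0, 1]`.
#' @inheritParams profile_shape
#' @return Normalized radii in `[0, 1]`.
#' @export
flux_radius <- function(q, n, wall_mode = c("no_slip", "slip")) {
  wall_mode <- match.arg(wall_mode)
  if (any(q < 0 | q > 1)) stop("flux fraction must lie in [0, 1]")
  if (wall_mode == "slip") return(sqrt(q))
  grid <- seq(0, 1, length.out = 2049L)
  xi <- stats::approx(flux_fraction(grid, n, wall_mode), grid, xout = q,
                      rule = 2)$y
  m <- (n + 1) / n
  cpre <- (3 * n + 1) / (n + 1)
  for (it in 1:4) {                     # Newton polish; F' = 2 phi xi
    f <- flux_fraction(xi, n, wall_mode) - q
    fp <- 2 * cpre * (1 - xi^m) * xi
    step <- ifelse(fp > 1e-12, f / fp, 0)
    xi <- pmin(1, pmax(0, xi - step))
  }
  xi
}

# (F(xi) - xi^2) / (2 xi) with the xi -> 0 limit handled; radial-velocity
# shape factor of the piston healing zone.
radial_shape_factor <- function(xi, n, wall_mode) {
  out <- numeric(length(xi))
  small <- xi < 1e-10
  Fx <- flux_fraction(pmax(xi, 1e-10), n, wall_mode)
  out[!small] <- (Fx[!small] - xi[!small]^2) / (2 * xi[!small])
  out
}

#' Quasi-steady axisymmetric velocity field
#'
#' Builds the reduced-order (lubrication-style) velocity field of the
#' piston-driven cartridge. At axial position `z` with local radius `R(z)` the
#' axial velocity is `U(z) * phi(r/R(z))` with `U(z) = Q / (pi R(z)^2)` and
#' `Q = v pi R_b^2`; the radial component follows from incompressibility
#' (streamlines are lines of constant normalized radius in the cone). Within a
#' healing length `healing_length` of the piston crown the barrel profile is
#' blended to the plug motion of the crown, `u_z = v + (U phi - v) w(s)`,
#' `w(s) = 1 - exp(-s / healing_length)` with `s` the distance ahead of the
#' crown, so that fluid is never overtaken by the piston; the corresponding
#' analytic `u_r` keeps the field volume conserving through every cross
#' section.
#'
#' @param geom A [cartridge_geometry].
#' @param settings An [extrusion_settings].
#' @param params A [power_law_params] (only `n` enters the kinematics).
#' @param healing_length Axial blending length at the piston crown, m.
#'   Defaults to the barrel radius (creeping-flow disturbance decay scale).
#' @return A `velocity_field` object: fields `Q` (m^3/s), `geom`, `settings`,
#'   and `velocity(r, z, piston_position)` returning `list(u_r, u_z)`.
#' @export
build_velocity_field <- function(geom, settings, params,
                                 healing_length = geom$barrel_radius) {
  stopifnot(inherits(geom, "cartridge_geometry"),
            inherits(settings, "extrusion_settings"),
            inherits(params, "power_law_params"))
  v <- settings$piston_speed
  n <- params$n
  mode <- settings$wall_mode
  Rb <- geom$barrel_radius
  zc <- geom$barrel_length
  ze <- zc + geom$cone_length
  Q <- v * pi * Rb^2
  ell <- healing_length
  Rslope <- (geom$outlet_radius - Rb) / geom$cone_length

  velocity <- function(r, z, piston_position = 0) {
    if (any(piston_position < 0 | piston_position > zc))
      stop("piston position beyond domain (must lie within the straight barrel)")
    if (any(z < piston_position - 1e-12) || any(z > ze + 1e-12))
      stop("z outside the fluid domain")
    z <- pmin(z, ze)
    R <- local_radius(geom, z)
    xi <- pmin(r / R, 1)
    if (any(r < 0) || any(r / R > 1 + 1e-9)) stop("r outside the fluid domain")
    phi <- profile_shape(xi, n, mode)
    in_cone <- z > zc
    U <- Q / (pi * R^2)
    s <- pmax(z - piston_position, 0)
    w <- 1 - exp(-s / ell)
    u_z <- ifelse(in_cone,
                  U * phi,
                  v + (v * phi - v) * w)
    u_r <- ifelse(in_cone,
                  U * phi * xi * Rslope,
                  -v * (exp(-s / ell) / ell) * Rb *
                    radial_shape_factor(xi, n, mode))
    list(u_r = u_r, u_z = u_z)
  }

  structure(list(Q = Q, geom = geom, settings = settings, params = params,
                 healing_length = ell, velocity = velocity),
            class = "velocity_field")
}

#' Integrate a streamline to the outlet plane
#'
#' Fourth-order Runge-Kutta integration of `dr/dt = u_r`, `dz/dt = u_z`
#' through a steady snapshot of the field (piston held at `piston_position`),
#' until the path reaches the outlet plane. Steps are halved adaptively near
#' the contraction; the exact outlet crossing is obtained by linear
#' interpolation of the last segment.
#'
#' @param field A `velocity_field` from [build_velocity_field].
#' @param start Numeric `(r0, z0)` starting point, m.
#' @param step Base time step, s. Defaults to `time_step / 20`.
#' @param piston_position Piston crown position, m (steady snapshot).
#' @param max_time Integration budget, s; exceeded paths raise a convergence
#'   error (e.g. wall-adjacent no-slip paths that barely move).
#' @return A data frame `(t, r, z)`; attribute `transit_time` holds the exit
#'   time.
#' @export
streamline <- function(field, start, step = field$settings$time_step / 20,
                       piston_position = 0,
                       max_time = 100 * (field$geom$barrel_length +
                                         field$geom$cone_length) /
                                  field$settings$piston_speed) {
  stopifnot(inherits(field, "velocity_field"), length(start) == 2L)
  geom <- field$geom
  ze <- geom$barrel_length + geom$cone_length
  zc <- geom$barrel_length
  r <- start[1]; z <- start[2]
  if (z < piston_position || z > ze || r < 0 || r > local_radius(geom, z))
    stop("start point outside the fluid domain")
  t <- 0
  out_t <- t; out_r <- r; out_z <- z
  vel <- function(r, z) {
    z <- pmax(pmin(z, ze), piston_position)
    r <- pmax(pmin(r, local_radius(geom, z)), 0)
    field$velocity(r, z, piston_position)
  }
  while (z < ze) {
    if (t > max_time)
      stop("streamline failed to reach the outlet within the time budget")
    h <- step
    # halve the step while a full step would jump across a sizeable part of
    # the contraction
    repeat {
      uz <- vel(r, z)$u_z
      if (z + uz * h <= zc || uz * h <= geom$cone_length / 8 || h < step / 256)
        break
      h <- h / 2
    }
    k1 <- vel(r, z)
    k2 <- vel(r + h / 2 * k1$u_r, z + h / 2 * k1$u_z)
    k3 <- vel(r + h / 2 * k2$u_r, z + h / 2 * k2$u_z)
    k4 <- vel(r + h * k3$u_r, z + h * k3$u_z)
    dr <- h / 6 * (k1$u_r + 2 * k2$u_r + 2 * k3$u_r + k4$u_r)
    dz <- h / 6 * (k1$u_z + 2 * k2$u_z + 2 * k3$u_z + k4$u_z)
    if (dz <= 0)
      stop("streamline stalled before reaching the outlet")
    r_new <- pmax(r + dr, 0)
    z_new <- z + dz
    if (z_new >= ze) {
      frac <- (ze - z) / dz
      t <- t + frac * h
      r <- r + frac * dr
      z <- ze
    } else {
      t <- t + h
      r <- r_new
      z <- z_new
    }
    r <- pmin(r, local_radius(geom, z))
    out_t <- c(out_t, t); out_r <- c(out_r, r); out_z <- c(out_z, z)
  }
  path <- data.frame(t = out_t, r = out_r, z = out_z)
  attr(path, "transit_time") <- t
  path
}

#' Cross-section volumetric flux of a velocity field
#'
#' Numerically integrates \eqn{2\pi\int_0^{R(z)} u_z(r,z)\,r\,dr} at a given
#' axial station; used to verify volume conservation.
#'
#' @param field A `velocity_field`.
#' @param z Axial station, m.
#' @param piston_position Piston position, m.
#' @return Volumetric flux, m^3/s.
#' @export
section_flux <- function(field, z, piston_position = 0) {
  R <- local_radius(field$geom, z)
  f <- function(r) field$velocity(r, rep(z, length(r)), piston_position)$u_z * r
  2 * pi * stats::integrate(f, 0, R, rel.tol = 1e-10)$value
}
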