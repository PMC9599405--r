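trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# trapezoid quadrature mass attached to each sample of a (possibly nonuniform)
# time grid
sample_masses <- function(x) {
  d <- diff(x)
  c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
}

#' Transient AB-block extrusion simulation (Lagrangian marker engine)
#'
#' Simulates the extrusion of an AB block system from a cartridge. The flat
#' A/B interface is seeded with markers on an equal-flux radial grid (plus
#' axis and wall contact points) and advected through the quasi-steady
#' velocity field of [build_velocity_field] by vectorized RK4. Material
#' accounting is volumetric and exact: the in-barrel volume of material A at
#' any time is the axisymmetric quadrature of the column between the marker
#' surface and the accounting plane, and the reported outlet concentration of
#' each reporting step is the flow-averaged fraction
#' \eqn{C_A = \Delta V_A / (Q\,\Delta t)} delivered during that step, so the
#' series telescopes to the initial block-A volume when the piston crown
#' reaches the plane. Accounting happens at the cone entrance plane; the
#' conical tip acts as a composition-preserving delay line whose hold-up
#' volume and delay are reported as metadata. The run terminates when the
#' piston crown reaches the cone entrance, after `(block_A + block_B) /
#' piston_speed` seconds.
#'
#' @param geom A [cartridge_geometry].
#' @param fill A [block_fill]; block A sits on the outlet side.
#' @param settings An [extrusion_settings] (`wall_mode`, piston speed, output
#'   time step).
#' @param params A [power_law_params].
#' @param n_markers Number of interior interface markers (equal-flux annuli).
#' @param substeps RK4 substeps per output time step.
#' @param snapshot_times Times (s) at which outlet cross-section snapshots are
#'   recorded; default `c(0.25, 0.5, 0.75, 0.9, 0.97)` of the run duration.
#' @param n_annuli Number of equal-flux annuli in each snapshot.
#' @param healing_length Piston-crown blending length, m (see
#'   [build_velocity_field]).
#' @return An `extrusion_run` object: `series` (an `outlet_series` data frame
#'   with columns `time_s`, `Q_m3_s`, `C_A`, `C_B`), `snapshots` (list of
#'   `cross_section`), extruded volumes, cone hold-up metadata, and the input
#'   objects.
#' @export
simulate_extrusion <- function(geom, fill, settings, params,
                               n_markers = 512L, substeps = 20L,
                               snapshot_times = NULL, n_annuli = 16L,
                               healing_length = geom$barrel_radius) {
  stopifnot(inherits(geom, "cartridge_geometry"),
            inherits(fill, "block_fill"),
            inherits(settings, "extrusion_settings"),
            inherits(params, "power_law_params"))
  L <- fill$block_A + fill$block_B
  if (L > geom$barrel_length + 1e-12)
    stop("fill does not fit inside the straight barrel")
  v <- settings$piston_speed
  dt <- settings$time_step
  mode <- settings$wall_mode
  n <- params$n
  Rb <- geom$barrel_radius
  ell <- healing_length
  Q <- v * pi * Rb^2
  T_end <- L / v
  h <- dt / substeps
  if (h * max(profile_shape(0, n, mode), 1) * v > 0.5 * ell)
    stop("marker substep too coarse for the healing zone; increase substeps")

  # interface markers: equal-flux interior annuli (mid-annulus positions)
  # refined by equal-area markers in the outer 10% of the cross-section area
  # (the near-wall film is flux-starved but volume-rich), plus explicit axis
  # and wall contact points for the radial quadrature
  N <- as.integer(n_markers)
  q_mid <- (seq_len(N) - 0.5) / N
  xi <- flux_radius(q_mid, n, mode)
  n_wall <- max(16L, N %/% 8L)
  xi_wall <- sqrt(seq(0.9, 1, length.out = n_wall + 2L))
  xi_wall <- xi_wall[-c(1L, n_wall + 2L)]
  xi_all <- c(xi, xi_wall)
  r <- c(0, xi_all * Rb, Rb)
  z <- rep(fill$block_B, length(r))  # piston starts at z = 0; plane at z = L
  interior <- seq_along(xi_all) + 1L
  q_seed <- flux_fraction(xi_all, n, mode)   # tube identity of each marker

  phi_of <- function(r) profile_shape(pmin(r / Rb, 1), n, mode)
  g_of <- function(r) radial_shape_factor(pmin(r / Rb, 1), n, mode)
  # barrel field with the moving-crown healing zone (time dependent)
  ufun <- function(r, z, t) {
    s <- pmax(z - v * t, 0)
    e <- exp(-s / ell)
    list(u_r = -v * (e / ell) * Rb * g_of(r),
         u_z = v + v * (phi_of(r) - 1) * (1 - e))
  }

  # in-barrel volume of material A: 2*pi * integral r * max(L - z_I(r), 0) dr
  # over the marker polyline (markers stay radially ordered)
  a_inside <- function(r, z) {
    ord <- order(r)
    rr <- r[ord]
    zz <- pmax(L - pmin(z[ord], L), 0)
    f <- 2 * pi * rr * zz
    sum(diff(rr) * (f[-1] + f[-length(f)]) / 2)
  }

  times <- seq(0, T_end, by = dt)
  if (times[length(times)] < T_end - 1e-12) times <- c(times, T_end)
  if (is.null(snapshot_times))
    snapshot_times <- T_end * c(0.25, 0.5, 0.75, 0.9, 0.97)
  snapshot_times <- sort(snapshot_times[snapshot_times >= 0 &
                                          snapshot_times <= T_end])

  A_in <- numeric(length(times))
  A_in[1] <- a_inside(r, z)               # = pi R_b^2 L_A at t = 0
  snaps_alive <- vector("list", length(snapshot_times))

  t <- 0
  k_out <- 1L
  k_snap <- 1L
  n_steps <- as.integer(ceiling(T_end / h - 1e-9))
  fine_t <- numeric(n_steps + 1L)
  fine_A <- numeric(n_steps + 1L)
  fine_A[1] <- A_in[1]
  for (step in seq_len(n_steps)) {
    hh <- min(h, T_end - t)
    k1 <- ufun(r, z, t)
    k2 <- ufun(r + hh / 2 * k1$u_r, z + hh / 2 * k1$u_z, t + hh / 2)
    k3 <- ufun(r + hh / 2 * k2$u_r, z + hh / 2 * k2$u_z, t + hh / 2)
    k4 <- ufun(r + hh * k3$u_r, z + hh * k3$u_z, t + hh)
    r <- pmin(pmax(r + hh / 6 * (k1$u_r + 2 * k2$u_r + 2 * k3$u_r + k4$u_r), 0), Rb)
    z <- z + hh / 6 * (k1$u_z + 2 * k2$u_z + 2 * k3$u_z + k4$u_z)
    t <- t + hh
    fine_t[step + 1L] <- t
    fine_A[step + 1L] <- a_inside(r, z)
    while (k_snap <= length(snapshot_times) &&
           snapshot_times[k_snap] <= t + 1e-12) {
      snaps_alive[[k_snap]] <- z[interior] < L
      k_snap <- k_snap + 1L
    }
    while (k_out < length(times) && times[k_out + 1L] <= t + 1e-12) {
      k_out <- k_out + 1L
      A_in[k_out] <- fine_A[step + 1L]
    }
  }
  if (k_out < length(times)) A_in[(k_out + 1L):length(times)] <- fine_A[n_steps + 1L]

  # flow-averaged outlet composition per reporting step (telescopes to the
  # initial block-A volume); the t = 0 sample is the instantaneous value
  dV_A <- -diff(A_in)
  C_A <- c(1, dV_A / (Q * diff(times)))
  C_A <- pmin(pmax(C_A, 0), 1)

  series <- structure(
    data.frame(time_s = times, Q_m3_s = Q, C_A = C_A, C_B = 1 - C_A),
    class = c("outlet_series", "data.frame"))

  group <- ceiling(q_seed * n_annuli - 1e-12)
  ann_edges_xi <- flux_radius(seq(0, 1, length.out = n_annuli + 1L), n, mode)
  Ro <- geom$outlet_radius
  snapshots <- lapply(seq_along(snapshot_times), function(j) {
    ca <- tapply(snaps_alive[[j]], group, mean)
    xs <- structure(
      data.frame(r_inner_m = Ro * ann_edges_xi[-(n_annuli + 1L)],
                 r_outer_m = Ro * ann_edges_xi[-1L],
                 C_A = as.numeric(ca)),
      class = c("cross_section", "data.frame"))
    attr(xs, "time_s") <- snapshot_times[j]
    attr(xs, "flux_per_annulus") <- 1 / n_annuli
    xs
  })

  cone_holdup <- pi * geom$cone_length / 3 *
    (geom$barrel_radius^2 + geom$barrel_radius * geom$outlet_radius +
       geom$outlet_radius^2)
  V_A <- A_in[1] - A_in[length(A_in)]
  V_B <- Q * T_end - V_A

  structure(list(series = series, snapshots = snapshots,
                 geom = geom, fill = fill, settings = settings,
                 params = params,
                 duration_s = T_end,
                 extruded_volume_A_m3 = V_A,
                 extruded_volume_B_m3 = V_B,
                 fill_volume_A_m3 = pi * Rb^2 * fill$block_A,
                 fill_volume_B_m3 = pi * Rb^2 * fill$block_B,
                 residual_A_in_barrel_m3 = A_in[length(A_in)],
                 fine_times_s = fine_t,
                 fine_A_in_m3 = fine_A,
                 cone_holdup_m3 = cone_holdup,
                 cone_delay_s = cone_holdup / Q,
                 n_markers = N, substeps = as.integer(substeps)),
            class = "extrusion_run")
}

#' @export
print.extrusion_run <- function(x, ...) {
  cat(sprintf(
    paste0("AB-block extrusion run (%s): %.1f s, Q = %.3g mm^3/s\n",
           "  extruded A %.3g mm^3 (fill %.3g), B %.3g mm^3 (fill %.3g)\n",
           "  cone hold-up %.3g mm^3 (delay %.2f s), %d markers\n"),
    x$settings$wall_mode, x$duration_s, 1e9 * x$series$Q_m3_s[1],
    1e9 * x$extruded_volume_A_m3, 1e9 * x$fill_volume_A_m3,
    1e9 * x$extruded_volume_B_m3, 1e9 * x$fill_volume_B_m3,
    1e9 * x$cone_holdup_m3, x$cone_delay_s, x$n_markers))
  invisible(x)
}

#' Eulerian upwind finite-volume cross-check engine
#'
#' Independent oracle for [simulate_extrusion]: first-order upwind
#' finite-volume advection of the A-indicator on a fixed axisymmetric (r, z)
#' grid over the barrel fill, using the steady developed profile (no
#' piston-healing term) with pure-B inflow at the piston start plane. Like the
#' marker engine it reports the flow-averaged outlet concentration of each
#' reporting step (the `t = 0` sample is instantaneous); the advective
#' substeps are aligned with the reporting grid.
#'
#' @inheritParams simulate_extrusion
#' @param n_r,n_z Radial and axial cell counts.
#' @param dt_fv Advective time step, s; `NULL` (default) picks the largest
#'   integer fraction of the reporting step within 0.8 of the CFL limit. A
#'   supplied value violating the CFL condition is refused with guidance.
#' @return An `outlet_series` data frame (`time_s`, `Q_m3_s`, `C_A`, `C_B`).
#' @export
simulate_extrusion_fv <- function(geom, fill, settings, params,
                                  n_r = 64L, n_z = 256L, dt_fv = NULL) {
  stopifnot(inherits(geom, "cartridge_geometry"),
            inherits(fill, "block_fill"),
            inherits(settings, "extrusion_settings"),
            inherits(params, "power_law_params"))
  L <- fill$block_A + fill$block_B
  if (L > geom$barrel_length + 1e-12)
    stop("fill does not fit inside the straight barrel")
  v <- settings$piston_speed
  dt <- settings$time_step
  Rb <- geom$barrel_radius
  T_end <- L / v
  dz <- L / n_z
  r_mid <- (seq_len(n_r) - 0.5) * Rb / n_r
  u <- v * profile_shape(r_mid / Rb, params$n, settings$wall_mode)
  cfl_dt <- dz / max(u)
  if (is.null(dt_fv)) {
    m_sub <- max(1L, as.integer(ceiling(dt / (0.8 * cfl_dt))))
  } else {
    if (dt_fv > cfl_dt)
      stop(sprintf(
        "dt_fv = %.4g s violates the CFL condition (limit %.4g s); reduce dt_fv",
        dt_fv, cfl_dt))
    m_sub <- max(1L, as.integer(ceiling(dt / dt_fv)))
  }
  hh <- dt / m_sub

  z_mid <- (seq_len(n_z) - 0.5) * dz
  frac_A <- pmin(pmax((z_mid + dz / 2 - fill$block_B) / dz, 0), 1)
  conc <- matrix(rep(frac_A, each = n_r), nrow = n_r)
  wflux <- u * r_mid
  wflux <- wflux / sum(wflux)
  out_now <- function() sum(wflux * conc[, n_z])

  times <- seq(0, T_end, by = dt)
  if (times[length(times)] < T_end - 1e-12) times <- c(times, T_end)
  C_A <- numeric(length(times))
  C_A[1] <- out_now()
  cour <- u / dz
  t <- 0
  for (k in 2:length(times)) {
    dt_k <- times[k] - times[k - 1L]
    n_sub <- max(1L, as.integer(round(dt_k / hh)))
    h_k <- dt_k / n_sub
    acc <- out_now() / 2
    for (s in seq_len(n_sub)) {
      upstream <- cbind(0, conc[, -n_z, drop = FALSE])
      conc <- conc - (cour * h_k) * (conc - upstream)
      acc <- acc + if (s < n_sub) out_now() else out_now() / 2
    }
    C_A[k] <- acc / n_sub                    # trapezoid time average
  }
  C_A <- pmin(pmax(C_A, 0), 1)
  structure(
    data.frame(time_s = times, Q_m3_s = v * pi * Rb^2, C_A = C_A,
               C_B = 1 - C_A),
    class = c("outlet_series", "data.frame"))
}

#' Map an outlet time series onto printed-strand arc length
#'
#' Affine kinematic mapping `s = print_speed * t`; concentrations carry over
#' unchanged. The deposited volume per unit strand length, `Q / print_speed`,
#' is attached as metadata.
#'
#' @param series An `outlet_series` (or an `extrusion_run`).
#' @param print_speed Print-head speed, m/s.
#' @return A `strand_profile` data frame (`s_m`, `C_A`) with attribute
#'   `volume_per_length_m2`.
#' @export
outlet_to_strand <- function(series, print_speed) {
  if (inherits(series, "extrusion_run")) series <- series$series
  stopifnot(is.data.frame(series), nrow(series) >= 1L)
  if (!is.numeric(print_speed) || print_speed <= 0)
    stop("print_speed must be positive")
  out <- structure(
    data.frame(s_m = print_speed * series$time_s, C_A = series$C_A),
    class = c("strand_profile", "data.frame"))
  attr(out, "volume_per_length_m2") <- series$Q_m3_s[1] / print_speed
  out
}

#' Strand profile container
#'
#' Concentration (or fluorescence intensity) versus arc length along a printed
#' strand. Positions must be strictly increasing and start at zero.
#'
#' @param s Arc-length positions, m.
#' @param value Concentration fractions or intensities.
#' @return A `strand_profile` data frame (`s_m`, `C_A`).
#' @export
strand_profile <- function(s, value) {
  stopifnot(is.numeric(s), is.numeric(value), length(s) == length(value))
  if (length(s) < 2L) stop("a strand profile needs at least 2 samples")
  if (abs(s[1]) > 1e-12) stop("strand positions must start at 0")
  if (any(diff(s) <= 0)) stop("strand positions must be strictly increasing")
  structure(data.frame(s_m = s, C_A = value),
            class = c("strand_profile", "data.frame"))
}

#' Residual wall-material fraction
#'
#' Fraction of the extruded material A that leaves the cartridge after the
#' outlet concentration `C_A` first falls below `threshold`. Under no-slip
#' walls this captures the residual near-wall film of material A that is only
#' flushed out when the piston crown arrives; in the free-slip plug limit the
#' outlet series is a step and the fraction is zero.
#'
#' @param x An `extrusion_run` or `outlet_series`. For a run object the
#'   engine's full-resolution (substep) record of the in-barrel A volume is
#'   used, so the brief end-of-run flush is resolved even when the reporting
#'   step is coarse.
#' @param threshold Concentration threshold (default 0.01).
#' @return Fraction in `[0, 1]`. If `C_A` never falls below the threshold, 0
#'   is returned with a warning.
#' @export
residual_wall_fraction <- function(x, threshold = 0.01) {
  if (inherits(x, "extrusion_run")) {
    Q <- x$series$Q_m3_s[1]
    tt <- x$fine_times_s
    C_A <- c(1, -diff(x$fine_A_in_m3) / (Q * diff(tt)))
    series <- data.frame(time_s = tt, C_A = pmin(pmax(C_A, 0), 1))
  } else {
    series <- x
  }
  stopifnot(is.data.frame(series), nrow(series) >= 2L)
  m <- sample_masses(series$time_s)
  wA <- m * series$C_A
  total <- sum(wA)
  if (total <= 0) return(0)
  idx <- which(series$C_A < threshold)
  if (length(idx) == 0L) {
    warning("C_A never falls below the threshold; returning 0")
    return(0)
  }
  sum(wA[seq(idx[1], length(wA))]) / total
}
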