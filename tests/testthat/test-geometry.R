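test_that("profile shapes match the closed forms and normalize to unit mean", {
  xi <- seq(0, 1, length.out = 101)
  # free slip: plug
  expect_equal(profile_shape(xi, 0.2025, "slip"), rep(1, 101))
  # no slip, Newtonian: parabolic Poiseuille, centerline twice the mean
  expect_equal(profile_shape(xi, 1, "no_slip"), 2 * (1 - xi^2),
               tolerance = 1e-12)
  expect_equal(profile_shape(0, 1, "no_slip"), 2)
  # wall value vanishes for any index
  for (n in c(0.1, 0.2025, 0.7, 1, 1.6))
    expect_equal(profile_shape(1, n, "no_slip"), 0)
  # flux-weighted mean is one: 2 * integral phi(xi) xi dxi = 1
  for (n in c(0.05, 0.2025, 0.5, 1, 1.5)) {
    for (mode in c("slip", "no_slip")) {
      I <- stats::integrate(function(s) 2 * profile_shape(s, n, mode) * s,
                            0, 1, rel.tol = 1e-12)$value
      expect_equal(I, 1, tolerance = 1e-9)
    }
  }
  expect_error(profile_shape(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the no-slip profile approaches plug flow as n -> 0", {
  xi <- seq(0, 0.9, length.out = 200)
  dev <- vapply(c(0.05, 0.02, 0.01),
                function(n) max(abs(profile_shape(xi, n, "no_slip") - 1)),
                numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.05)
})

test_that("cumulative flux fraction matches quadrature and inverts", {
  for (n in c(0.2025, 1)) {
    for (mode in c("slip", "no_slip")) {
      for (x in c(0.2, 0.5, 0.8, 1)) {
        I <- stats::integrate(function(s) 2 * profile_shape(s, n, mode) * s,
                              0, x, rel.tol = 1e-12)$value
        expect_equal(flux_fraction(x, n, mode), I, tolerance = 1e-9)
      }
      q <- c(0, 0.1, 0.5, 0.9, 0.999, 1)
      xi <- flux_radius(q, n, mode)
      expect_equal(flux_fraction(xi, n, mode), q, tolerance = 1e-7)
    }
  }
})

test_that("geometry constructors validate and the radius profile tapers", {
  geom <- cartridge_geometry(needle_gauge = 20)
  expect_equal(geom$outlet_radius, 0.603e-3 / 2)
  expect_equal(gauge_inner_diameter(14), 1.60e-3)
  expect_error(cartridge_geometry(outlet_radius = 6e-3), "R_o < R_b")
  expect_error(gauge_inner_diameter(18), "unknown")
  expect_equal(local_radius(geom, c(0, 30e-3, 55e-3)), rep(4.8e-3, 3))
  expect_equal(local_radius(geom, 63e-3), geom$outlet_radius)
  expect_equal(local_radius(geom, 59e-3),
               (4.8e-3 + geom$outlet_radius) / 2, tolerance = 1e-12)
  expect_error(local_radius(geom, 70e-3), "domain")
  expect_error(block_fill(30e-3, 30e-3, geom), "does not fit")
})

test_that("the velocity field is volume conserving through every section", {
  geom <- cartridge_geometry()
  params <- silk_params()
  for (mode in c("slip", "no_slip")) {
    settings <- extrusion_settings(wall_mode = mode)
    field <- build_velocity_field(geom, settings, params)
    fluxes <- vapply(c(5e-3, 20e-3, 54e-3, 57e-3, 61e-3, 62.9e-3),
                     function(z) section_flux(field, z, piston_position = 2e-3),
                     numeric(1))
    expect_equal(fluxes / field$Q, rep(1, length(fluxes)), tolerance = 1e-8)
    # also inside the piston healing zone
    expect_equal(section_flux(field, 22e-3, piston_position = 20e-3) / field$Q,
                 1, tolerance = 1e-8)
  }
})

test_that("field limits: slip plug and Newtonian Poiseuille", {
  geom <- cartridge_geometry()
  params <- silk_params()
  fs <- build_velocity_field(geom, extrusion_settings(wall_mode = "slip"),
                             params)
  r <- seq(0, geom$barrel_radius, length.out = 7)
  uv <- fs$velocity(r, rep(10e-3, 7), 0)
  expect_equal(uv$u_z, rep(5e-3, 7))
  expect_equal(uv$u_r, rep(0, 7))
  # developed no-slip Newtonian profile (healing switched off)
  fn <- build_velocity_field(geom, extrusion_settings(wall_mode = "no_slip"),
                             power_law_params(10, 1), healing_length = 1e-9)
  uz <- fn$velocity(r, rep(30e-3, 7), 0)$u_z
  expect_equal(uz, 2 * 5e-3 * (1 - (r / geom$barrel_radius)^2),
               tolerance = 1e-12)
  expect_error(fn$velocity(1e-3, 30e-3, 60e-3), "beyond domain")
  expect_error(fn$velocity(6e-3, 30e-3, 0), "outside")
})

test_that("streamlines behave: plug transit, axis symmetry, wall ordering", {
  params <- silk_params()
  # near-degenerate straight-tube geometry, slip: pure plug kinematics
  p <- plug_setup()
  fs <- build_velocity_field(p$geom, p$settings, params)
  ze <- p$geom$barrel_length + p$geom$cone_length
  path <- streamline(fs, c(2e-3, 10e-3))
  expect_equal(attr(path, "transit_time"), (ze - 10e-3) / 5e-3,
               tolerance = 1e-6)

  # full geometry, no slip
  geom <- cartridge_geometry()
  fn <- build_velocity_field(geom, extrusion_settings(wall_mode = "no_slip"),
                             params)
  # axis streamline stays on the axis
  ax <- streamline(fn, c(0, 10e-3))
  expect_true(all(ax$r == 0))
  # transit time is non-decreasing in starting radius
  r0 <- seq(0, 0.9, by = 0.15) * geom$barrel_radius
  tt <- vapply(r0, function(r)
    attr(streamline(fn, c(r, 30e-3)), "transit_time"), numeric(1))
  expect_true(all(diff(tt) >= 0))
  # paths never cross the wall
  for (r in c(0.3, 0.8) * geom$barrel_radius) {
    pth <- streamline(fn, c(r, 30e-3))
    expect_true(all(pth$r <= local_radius(geom, pth$z) + 1e-12))
  }
  # wall-adjacent no-slip path exhausts the budget
  expect_error(streamline(fn, c(0.99999 * geom$barrel_radius, 5e-3),
                          max_time = 10), "budget")
  expect_error(streamline(fn, c(1e-3, 70e-3)), "outside")
})
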