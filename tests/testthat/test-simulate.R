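test_that("degenerate plug extrusion yields an exact step outlet series", {
  run <- cached_plug_run()
  s <- run$series
  t_step <- run$fill$block_A / run$settings$piston_speed
  expect_equal(s$C_A[s$time_s <= t_step + 1e-9],
               rep(1, sum(s$time_s <= t_step + 1e-9)), tolerance = 1e-9)
  expect_equal(s$C_A[s$time_s > t_step + 1e-9],
               rep(0, sum(s$time_s > t_step + 1e-9)), tolerance = 1e-9)
  expect_equal(run$extruded_volume_A_m3 / run$extruded_volume_B_m3, 0.5,
               tolerance = 1e-9)
  expect_equal(residual_wall_fraction(run), 0)
})

test_that("mass conservation: extruded A equals the initial block volume", {
  run <- cached_default_run()
  s <- run$series
  # telescoped volumetric accounting is exact
  expect_equal(run$extruded_volume_A_m3, run$fill_volume_A_m3,
               tolerance = 1e-9)
  # the reported series integrates to the same volume (sum C_A * Q * dt)
  V_sum <- sum(s$C_A[-1] * s$Q_m3_s[-1] * diff(s$time_s))
  expect_equal(V_sum, pi * run$geom$barrel_radius^2 * run$fill$block_A,
               tolerance = 1e-2)
  # C_A + C_B = 1 at every time point
  expect_equal(s$C_A + s$C_B, rep(1, nrow(s)))
  # total extruded volume equals the initial fill volume
  expect_equal(run$extruded_volume_A_m3 + run$extruded_volume_B_m3,
               run$fill_volume_A_m3 + run$fill_volume_B_m3, tolerance = 1e-9)
})

test_that("conservation tightens with refined resolution", {
  cfg <- default_run_config()
  run <- simulate_extrusion(cfg$geom, cfg$fill, cfg$settings, cfg$params,
                            n_markers = 1024L, substeps = 40L)
  V_sum <- sum(run$series$C_A[-1] * run$series$Q_m3_s[-1] *
                 diff(run$series$time_s))
  expect_equal(V_sum, run$fill_volume_A_m3, tolerance = 1e-3)
})

test_that("extruded volumes honour the fill ratio in both wall modes", {
  cfg <- default_run_config()
  run <- cached_default_run()
  expect_equal(run$extruded_volume_A_m3 / run$extruded_volume_B_m3,
               cfg$fill$block_A / cfg$fill$block_B, tolerance = 1e-9)
  # reversed fill inverts the ratio
  rev_fill <- block_fill(cfg$fill$block_B, cfg$fill$block_A, cfg$geom)
  run_rev <- simulate_extrusion(cfg$geom, rev_fill, cfg$settings, cfg$params)
  expect_equal(run_rev$extruded_volume_A_m3 / run_rev$extruded_volume_B_m3,
               cfg$fill$block_B / cfg$fill$block_A, tolerance = 1e-9)
})

test_that("no-slip crossover is a monotone sigmoid before the crown flush", {
  run <- cached_default_run()
  s <- run$series
  # residual-tail phase: the last ~3 healing lengths of piston travel
  t_flush <- run$duration_s -
    3 * run$geom$barrel_radius / run$settings$piston_speed
  pre <- s$C_A[s$time_s <= t_flush]
  expect_equal(pre[1], 1)
  expect_true(all(diff(pre) <= 1e-6))
  # nonzero 90%-to-10% transition interval
  t90 <- s$time_s[which(s$C_A < 0.9)[1]]
  t10 <- s$time_s[which(s$C_A < 0.1)[1]]
  expect_gt(t10 - t90, 2 * run$settings$time_step)
})

test_that("late no-slip cross sections show an A-rich shell", {
  run <- cached_default_run()
  # snapshots default to fractions of the duration; use the 0.9 T one
  ts <- vapply(run$snapshots, attr, numeric(1), "time_s")
  late <- run$snapshots[[which.min(abs(ts - 0.9 * run$duration_s))]]
  expect_gt(core_shell_statistic(late), 0)
  # annuli partition [0, R_o]
  expect_equal(late$r_inner_m[1], 0)
  expect_equal(late$r_outer_m[nrow(late)], run$geom$outlet_radius)
  expect_equal(late$r_inner_m[-1], late$r_outer_m[-nrow(late)])
  expect_true(all(late$C_A >= 0 & late$C_A <= 1))
})

test_that("residual wall material: flush tail in no-slip, none in plug flow", {
  run <- cached_default_run()
  expect_gt(residual_wall_fraction(run), 0)
  expect_equal(residual_wall_fraction(cached_plug_run()), 0)
  # degenerate threshold captures (almost) everything after the first decline
  expect_gt(residual_wall_fraction(run, threshold = 1.0), 0.9)
  # a series that never crosses the threshold warns and returns 0
  flat <- structure(data.frame(time_s = 0:5, Q_m3_s = 1,
                               C_A = rep(0.5, 6), C_B = rep(0.5, 6)),
                    class = c("outlet_series", "data.frame"))
  expect_warning(out <- residual_wall_fraction(flat, 0.01), "never")
  expect_equal(out, 0)
})

test_that("marker and finite-volume engines agree on a coarse problem", {
  geom <- cartridge_geometry()
  fill <- block_fill(8e-3, 16e-3, geom)
  settings <- extrusion_settings(wall_mode = "no_slip")
  params <- silk_params()
  run <- simulate_extrusion(geom, fill, settings, params, n_markers = 256L)
  fv <- simulate_extrusion_fv(geom, fill, settings, params,
                              n_r = 32L, n_z = 128L)
  expect_equal(fv$time_s, run$series$time_s)
  expect_lt(mean(abs(run$series$C_A - fv$C_A)), 0.03)
})

test_that("the FV oracle refuses CFL-violating time steps", {
  cfg <- default_run_config()
  expect_error(simulate_extrusion_fv(cfg$geom, cfg$fill, cfg$settings,
                                     cfg$params, dt_fv = 1),
               "CFL")
})

test_that("outlet-to-strand mapping is affine kinematics", {
  # a synthetic 10 s step series printed at 20 mm/s spans 0.200 m
  times <- seq(0, 10, by = 0.1)
  series <- structure(
    data.frame(time_s = times, Q_m3_s = 3.6e-7,
               C_A = as.numeric(times <= 4), C_B = as.numeric(times > 4)),
    class = c("outlet_series", "data.frame"))
  strand <- outlet_to_strand(series, 20e-3)
  expect_equal(max(strand$s_m), 0.200)
  expect_equal(strand$C_A, series$C_A)
  # the step maps to s = print_speed * t_step
  expect_equal(strand$s_m[which(strand$C_A == 0)[1] - 1L], 20e-3 * 4)
  # halving the print speed halves every position
  expect_equal(outlet_to_strand(series, 10e-3)$s_m, strand$s_m / 2)
  expect_equal(attr(strand, "volume_per_length_m2"), 3.6e-7 / 20e-3)
  expect_error(outlet_to_strand(series, 0), "positive")
})

test_that("simulation inputs are validated", {
  cfg <- default_run_config()
  big <- list(block_A = 40e-3, block_B = 40e-3)
  class(big) <- "block_fill"
  expect_error(simulate_extrusion(cfg$geom, big, cfg$settings, cfg$params),
               "fit")
  expect_error(simulate_extrusion(cfg$geom, cfg$fill, cfg$settings,
                                  cfg$params, substeps = 1L,
                                  healing_length = 1e-5),
               "substep")
})
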