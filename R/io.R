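#' Read a flow-curve CSV
#'
#' Expects a header with columns `shear_rate_per_s` and `shear_stress_Pa`;
#' alternatively a `viscosity_Pa_s` column is accepted and converted on read
#' (`tau = eta * gamma_dot`). Lines starting with `#` are comments.
#'
#' @param path CSV file path.
#' @return A [flow_curve].
#' @export
read_flow_curve <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"shear_rate_per_s" %in% names(df))
    stop("flow-curve CSV must have a 'shear_rate_per_s' column")
  if ("shear_stress_Pa" %in% names(df)) {
    tau <- df$shear_stress_Pa
  } else if ("viscosity_Pa_s" %in% names(df)) {
    tau <- df$viscosity_Pa_s * df$shear_rate_per_s
  } else {
    stop("flow-curve CSV needs a 'shear_stress_Pa' or 'viscosity_Pa_s' column")
  }
  ord <- order(df$shear_rate_per_s)
  flow_curve(df$shear_rate_per_s[ord], tau[ord])
}

#' Write a flow curve as CSV
#' @param curve A [flow_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flow_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(shear_rate_per_s = curve$shear_rate,
               shear_stress_Pa = curve$shear_stress),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an outlet series as CSV (`time_s,Q_m3_s,C_A,C_B`)
#' @param series An `outlet_series` or `extrusion_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outlet_series <- function(series, path) {
  if (inherits(series, "extrusion_run")) series <- series$series
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an outlet series CSV
#' @param path CSV path with columns `time_s,Q_m3_s,C_A,C_B`.
#' @return An `outlet_series` data frame.
#' @export
read_outlet_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("time_s", "Q_m3_s", "C_A") %in% names(df)))
  if (is.null(df$C_B)) df$C_B <- 1 - df$C_A
  structure(df, class = c("outlet_series", "data.frame"))
}

#' Write a strand profile as CSV (`s_m,C_A`)
#' @param strand A `strand_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strand_profile <- function(strand, path) {
  utils::write.csv(strand[, c("s_m", "C_A")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a strand profile CSV
#' @param path CSV path with columns `s_m,C_A` (or position/value in the
#'   first two columns).
#' @return A `strand_profile`.
#' @export
read_strand_profile <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("s_m", "C_A") %in% names(df))) {
    names(df)[1:2] <- c("s_m", "C_A")
  }
  strand_profile(df$s_m, df$C_A)
}

#' Write cross-section snapshots in long CSV format
#'
#' Columns `time_s,r_inner_m,r_outer_m,C_A`, one block of rows per snapshot.
#'
#' @param snapshots List of `cross_section` objects (or an `extrusion_run`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(snapshots, path) {
  if (inherits(snapshots, "extrusion_run")) snapshots <- snapshots$snapshots
  long <- do.call(rbind, lapply(snapshots, function(xs)
    cbind(time_s = attr(xs, "time_s"), as.data.frame(xs))))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (JSON)
#'
#' Structured text configuration with millimetre-based keys:
#' `barrel_radius_mm`, `barrel_length_mm`, `cone_length_mm`,
#' `outlet_radius_mm` (or `needle_gauge`), `piston_speed_mm_s`, `time_step_s`,
#' `wall_mode`, `print_speed_mm_s`, `block_A_mm`, `block_B_mm`, and optionally
#' `k_Pa_sn`, `n`, `fit_range_per_s`. Missing keys fall back to the
#' [default_run_config] values.
#'
#' @param path JSON file path.
#' @return Named list `params`, `geom`, `fill`, `settings` (as
#'   [default_run_config]).
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- default_run_config()
  gv <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  outlet_radius <- if (!is.null(cfg$needle_gauge))
    gauge_inner_diameter(cfg$needle_gauge) / 2
  else gv("outlet_radius_mm", 1e3 * def$geom$outlet_radius) * 1e-3
  geom <- cartridge_geometry(
    barrel_radius = gv("barrel_radius_mm", 1e3 * def$geom$barrel_radius) * 1e-3,
    barrel_length = gv("barrel_length_mm", 1e3 * def$geom$barrel_length) * 1e-3,
    cone_length = gv("cone_length_mm", 1e3 * def$geom$cone_length) * 1e-3,
    outlet_radius = outlet_radius)
  fill <- block_fill(gv("block_A_mm", 1e3 * def$fill$block_A) * 1e-3,
                     gv("block_B_mm", 1e3 * def$fill$block_B) * 1e-3, geom)
  settings <- extrusion_settings(
    piston_speed = gv("piston_speed_mm_s", 1e3 * def$settings$piston_speed) * 1e-3,
    time_step = gv("time_step_s", def$settings$time_step),
    wall_mode = gv("wall_mode", def$settings$wall_mode),
    print_speed = gv("print_speed_mm_s", 1e3 * def$settings$print_speed) * 1e-3)
  params <- power_law_params(
    k = gv("k_Pa_sn", def$params$k),
    n = gv("n", def$params$n),
    fit_range = unlist(gv("fit_range_per_s", def$params$fit_range)))
  list(params = params, geom = geom, fill = fill, settings = settings)
}

#' Write the run manifest (full configuration + package version) as JSON
#'
#' @param run An `extrusion_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(run, path) {
  stopifnot(inherits(run, "extrusion_run"))
  manifest <- list(
    package = "gradink",
    version = as.character(utils::packageVersion("gradink")),
    geometry = list(barrel_radius_mm = 1e3 * run$geom$barrel_radius,
                    barrel_length_mm = 1e3 * run$geom$barrel_length,
                    cone_length_mm = 1e3 * run$geom$cone_length,
                    outlet_radius_mm = 1e3 * run$geom$outlet_radius),
    fill = list(block_A_mm = 1e3 * run$fill$block_A,
                block_B_mm = 1e3 * run$fill$block_B),
    settings = list(piston_speed_mm_s = 1e3 * run$settings$piston_speed,
                    time_step_s = run$settings$time_step,
                    wall_mode = run$settings$wall_mode,
                    print_speed_mm_s = 1e3 * run$settings$print_speed,
                    pneumatic_pressure_Pa = run$settings$pneumatic_pressure),
    rheology = list(k_Pa_sn = run$params$k, n = run$params$n,
                    fit_range_per_s = run$params$fit_range),
    engine = list(n_markers = run$n_markers, substeps = run$substeps,
                  duration_s = run$duration_s,
                  cone_holdup_mm3 = 1e9 * run$cone_holdup_m3,
                  cone_delay_s = run$cone_delay_s))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
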