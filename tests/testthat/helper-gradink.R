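# shared fixtures; heavier runs are cached across test files
.gradink_cache <- new.env(parent = emptyenv())

silk_params <- function() power_law_params(148.89, 0.2025, c(0.1, 10))

cached_default_run <- function() {
  if (is.null(.gradink_cache$run)) {
    cfg <- default_run_config()
    .gradink_cache$run <- simulate_extrusion(cfg$geom, cfg$fill,
                                             cfg$settings, cfg$params)
  }
  .gradink_cache$run
}

# degenerate plug geometry: near-uniform bore, vanishing cone, free slip
plug_setup <- function() {
  geom <- cartridge_geometry(outlet_radius = 4.8e-3 * 0.999,
                             cone_length = 1e-6)
  list(geom = geom,
       fill = block_fill(10e-3, 20e-3, geom),
       settings = extrusion_settings(wall_mode = "slip"),
       params = silk_params())
}

cached_plug_run <- function() {
  if (is.null(.gradink_cache$plug)) {
    p <- plug_setup()
    .gradink_cache$plug <- simulate_extrusion(p$geom, p$fill, p$settings,
                                              p$params)
  }
  .gradink_cache$plug
}
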