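# Shared fixtures: compact radar sites and lattices keep the full-volume
# simulations fast while preserving the geometry of the real scan pattern.

compact_site <- function(azimuth_step = 3,
                         elevation_angles = seq(0.5, 4, by = 1),
                         max_range = 45, ...) {
  radar_site(site_id = "syn", azimuth_step = azimuth_step,
             elevation_angles = elevation_angles, max_range = max_range, ...)
}

default_lattice <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_cvp_lattice(radar_site())
    cache
  }
})

compact_lattice_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      site <- compact_site()
      lat <- build_cvp_lattice(site)
      cache <<- list(site = site, lattice = lat,
                     mapping = assign_gates_to_columns(lat, site))
    }
    cache
  }
})

# noiseless single-class scene: the exact forward/inverse round-trip setting
noiseless_config <- function(seed = 1, ...) {
  scene_config(seed = seed, diel_curve = NULL, season_envelope = NULL,
               background = NULL,
               noise_sd = list(z = 0, zdr = 0, rhohv = 0), ...)
}
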