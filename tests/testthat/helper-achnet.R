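# shared fixtures and a cross-file cache for expensive simulations

.sim_cache <- new.env(parent = emptyenv())

sim_cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# default topology, built once
default_topo <- function() {
  sim_cached("topo_default", build_topology())
}

# a raster object from explicit spike times for one synthetic cell
raster_from_times <- function(times, duration, transient = 0, id = 1L,
                              n_E = 1L, n_I = 0L) {
  structure(list(events = data.frame(time = times, id = rep(id, length(times))),
                 duration = duration, transient = transient,
                 n_E = n_E, n_I = n_I), class = "spike_raster")
}

# phase-aligned periodic population raster: n_cells all firing at f Hz
periodic_population_raster <- function(f, n_cells = 400, duration = 5500,
                                       transient = 500) {
  tt <- seq(transient + 1000 / f, duration, by = 1000 / f)
  structure(list(events = data.frame(time = rep(tt, each = n_cells),
                                     id = rep(seq_len(n_cells), length(tt))),
                 duration = duration, transient = transient,
                 n_E = as.integer(n_cells), n_I = 0L),
            class = "spike_raster")
}

# double-hotspot reference scenario (Fig 4H / Fig 6 geometry), cached
double_hotspot_map <- function() {
  sim_cached("map_double", generate_gks_map(rbind(c(6L, 10L), c(14L, 10L)), 6.1))
}

double_hotspot_rasters <- function(seeds = 1:2, duration = 5500) {
  lapply(seeds, function(s)
    sim_cached(paste0("raster_double_", s, "_", duration),
      run_simulation(default_topo(), double_hotspot_map(),
                     noise = noise_config(enabled = TRUE),
                     cfg = sim_config(duration = duration), seed = s)))
}

# single-hotspot reference raster, cached
single_hotspot_raster <- function(radius = 4.2, seed = 1, duration = 4500) {
  key <- paste0("raster_single_", radius, "_", seed, "_", duration)
  sim_cached(key, {
    map <- sim_cached(paste0("map_single_", radius),
                      generate_gks_map(cbind(10L, 10L), radius))
    run_simulation(default_topo(), map, noise = noise_config(enabled = TRUE),
                   cfg = sim_config(duration = duration), seed = seed)
  })
}
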