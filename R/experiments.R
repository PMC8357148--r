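#' Declarative experiment specification
#'
#' A self-contained, serializable description of one simulation scenario:
#' the gKs map recipe, topology variant, drive/noise settings, simulation
#' window and requested analyses. Replicates (default 4) rerun the same
#' scenario from different random initial conditions (and, for random
#' maps, different site draws).
#'
#' @param name scenario name
#' @param map list describing the map recipe: `kind` in
#'   `"random"` (fields `n`, `radius`), `"sites"` (fields `sites` as a
#'   2-column matrix, `radius`), `"uniform"` (field `value`); optional
#'   `gks_min`, `I_gks_zero`
#' @param topology list of variant knobs: `rewire_p`, `inh_density`,
#'   `inh_w`, and synaptic overrides `wII`, `wIE`, `tau_inh`
#' @param drive list: `I_base`, optional `hotspots` (matrix of centers),
#'   `hotspot_radius`, `I_target`
#' @param noise list: `enabled`, `rate`, `amp`, `width`
#' @param sim list: `duration`, `transient`, `dt`
#' @param analyses character subset of `c("rhythm", "mi")`
#' @param mi_locations matrix of probe locations for the `"mi"` analysis
#' @param tau_z M-current time constant override (ms)
#' @param seeds integer replicate seeds
#' @return object of class `experiment_spec`
#' @export
experiment_spec <- function(name, map, topology = list(), drive = list(),
                            noise = list(), sim = list(),
                            analyses = "rhythm", mi_locations = NULL,
                            tau_z = 75, seeds = 1:4) {
  spec <- list(name = name, map = map, topology = topology, drive = drive,
               noise = noise, sim = sim, analyses = analyses,
               mi_locations = mi_locations, tau_z = tau_z,
               seeds = as.integer(seeds))
  structure(spec, class = "experiment_spec")
}

#' Serialize / parse an experiment spec (YAML round trip)
#'
#' @param spec `experiment_spec`
#' @return `serialize_spec`: YAML string; `parse_spec`: `experiment_spec`
#' @export
serialize_spec <- function(spec) {
  s <- unclass(spec)
  s$mi_locations <- if (is.null(s$mi_locations)) NULL else
    as.data.frame(s$mi_locations)
  if (!is.null(s$map$sites)) s$map$sites <- as.data.frame(s$map$sites)
  yaml::as.yaml(s, precision = 15)
}

#' @rdname serialize_spec
#' @param text YAML string
#' @export
parse_spec <- function(text) {
  s <- yaml::yaml.load(text)
  if (!is.null(s$mi_locations))
    s$mi_locations <- as.matrix(as.data.frame(s$mi_locations))
  if (!is.null(s$map$sites))
    s$map$sites <- as.matrix(as.data.frame(s$map$sites))
  s$seeds <- as.integer(s$seeds)
  do.call(experiment_spec, s)
}

#' Stable hash of an experiment spec
#'
#' MD5 of the YAML serialization; recorded with every output.
#'
#' @param spec `experiment_spec`
#' @return character hash
#' @export
spec_hash <- function(spec) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(serialize_spec(spec), tf)
  unname(tools::md5sum(tf))
}

# default double-hotspot site pair at distance d, centered on the lattice
.double_sites <- function(d, L = 20L) {
  x1 <- (L / 2 - round(d / 2)) %% L
  x2 <- (x1 + round(d)) %% L
  rbind(c(x1, L / 2), c(x2, L / 2))
}

# realize the gKs map of a spec for one replicate seed
.spec_map <- function(spec, seed) {
  m <- spec$map
  dflt <- gks_map_params()
  pars <- gks_map_params(
    D = if (is.null(m$D)) dflt$D else m$D,
    B = if (is.null(m$B)) dflt$B else m$B,
    R_amp = if (is.null(m$R_amp)) dflt$R_amp else m$R_amp,
    gks_min = if (is.null(m$gks_min)) 0.2 else m$gks_min)
  zi <- isTRUE(m$I_gks_zero)
  switch(m$kind,
    uniform = uniform_gks_map(m$value, I_gks_zero = zi),
    sites = generate_gks_map(m$sites, target_radius = m$radius,
                             params = pars, I_gks_zero = zi),
    single = generate_gks_map(cbind(10L, 10L), target_radius = m$radius,
                              params = pars, I_gks_zero = zi),
    double = generate_gks_map(.double_sites(m$d), target_radius = m$radius,
                              params = pars, I_gks_zero = zi),
    random = generate_gks_map(random_sites(m$n, seed = seed),
                              target_radius = m$radius, params = pars,
                              I_gks_zero = zi),
    stop("unknown map kind: ", m$kind))
}

# realize the topology of a spec
.spec_topology <- function(spec, seed) {
  tp <- spec$topology
  syn <- synapse_params(
    wII = if (is.null(tp$wII)) 0.04 else tp$wII,
    wIE = if (is.null(tp$wIE)) 0.04 else tp$wIE,
    tau_inh = if (is.null(tp$tau_inh)) 3.0 else tp$tau_inh)
  topo <- build_topology(syn = syn)
  if (!is.null(tp$rewire_p) && tp$rewire_p > 0)
    topo <- rewire_ee(topo, tp$rewire_p, seed = seed)
  if (!is.null(tp$inh_density) && tp$inh_density < 1)
    topo <- sparsify_inhibition(topo, tp$inh_density, tp$inh_w, seed = seed)
  topo
}

# realize the drive of a spec (optional current-drive hotspots)
.spec_drive <- function(spec, geom = lattice_geometry()) {
  dr <- spec$drive
  I_base <- if (is.null(dr$I_base)) 3.0 else dr$I_base
  if (is.null(dr$hotspots)) return(drive_config(I_base))
  ctr <- matrix(dr$hotspots, ncol = 2)
  pos <- cbind(rep(0:(geom$L_E - 1), each = geom$L_E),
               rep(0:(geom$L_E - 1), times = geom$L_E))
  d <- sapply(seq_len(nrow(ctr)), function(i)
    periodic_distance(pos, ctr[i, , drop = FALSE], geom$L_E))
  ids <- which(apply(matrix(d, ncol = nrow(ctr)), 1, min) <= dr$hotspot_radius)
  drive_config(I_base, target_ids = ids, I_target = dr$I_target)
}

#' Run one experiment end to end
#'
#' For each replicate seed: realize the map, topology and drive, simulate,
#' and run the requested analyses; then aggregate across replicates
#' (averaged E-population spectrum and its band peaks, mean label counts,
#' replicate-mean MI profile). Idempotent given the seeds.
#'
#' @param spec `experiment_spec`
#' @param keep_rasters retain the per-replicate rasters in the result
#' @return list with `spec`, `hash`, per-replicate `reports`, aggregated
#'   `spectrum`, `theta`, `gamma` band peaks, `counts` matrix, and `mi`
#'   profile when requested
#' @export
run_experiment <- function(spec, keep_rasters = FALSE) {
  sm <- spec$sim
  cfg <- sim_config(
    dt = if (is.null(sm$dt)) 0.05 else sm$dt,
    duration = if (is.null(sm$duration)) 5500 else sm$duration,
    transient = if (is.null(sm$transient)) 500 else sm$transient)
  nz <- spec$noise
  # Poisson pulse noise is on for scenario runs: it breaks the degenerate
  # fully synchronized network state that fixed-point initial conditions
  # can fall into, letting the competitive hotspot dynamics express
  noise <- noise_config(enabled = if (is.null(nz$enabled)) TRUE else
    isTRUE(nz$enabled))
  params <- neuron_params(tau_z = spec$tau_z)
  drive <- .spec_drive(spec)

  rasters <- list(); reports <- list(); spectra <- list()
  for (i in seq_along(spec$seeds)) {
    s <- spec$seeds[i]
    map <- .spec_map(spec, seed = s)
    topo <- .spec_topology(spec, seed = s)
    r <- run_simulation(topo, map, drive = drive, noise = noise,
                        cfg = cfg, params = params, seed = s)
    rasters[[i]] <- r
    spectra[[i]] <- network_spectrum(r, "E")
    if ("rhythm" %in% spec$analyses) reports[[i]] <- rhythm_report(r)
  }

  avg <- average_spectra(spectra)
  out <- list(spec = spec, hash = spec_hash(spec),
              spectrum = avg,
              theta = band_peak(avg, c(2.5, 20)),
              gamma = band_peak(avg, c(25, 100)),
              theta_significant = band_significant(avg, c(2.5, 20)),
              gamma_significant = band_significant(avg, c(25, 100)))
  if (length(reports)) {
    out$reports <- reports
    out$counts <- sapply(reports, function(rp) as.numeric(rp$counts))
    rownames(out$counts) <- names(reports[[1]]$counts)
  }
  if ("mi" %in% spec$analyses && !is.null(spec$mi_locations)) {
    centers <- switch(spec$map$kind,
                      sites = spec$map$sites,
                      single = cbind(10L, 10L),
                      double = .double_sites(spec$map$d),
                      stop("mi analysis needs explicit hotspot sites"))
    out$mi <- mi_distance_profile(rasters, centers, spec$mi_locations)
  }
  if (keep_rasters) out$rasters <- rasters
  out
}

#' Scan a parameter grid
#'
#' Runs `run_experiment` on a template spec with per-grid-point overrides
#' and collects summary metrics (band powers, peak frequencies, label
#' counts). Failures at individual grid points are recorded and the scan
#' continues.
#'
#' @param template `experiment_spec`
#' @param grid data.frame; each row is one grid point, columns name the
#'   fields to override using dotted paths (e.g. `map.radius`,
#'   `topology.rewire_p`, `drive.I_base`, `tau_z`)
#' @return data.frame: the grid plus `theta_power`, `theta_freq`,
#'   `gamma_power`, `gamma_freq`, `n_theta`, `n_gamma`, `n_mixed`,
#'   `n_none`, `error`
#' @export
run_scan <- function(template, grid) {
  res <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- template
    for (col in names(grid)) {
      path <- strsplit(col, ".", fixed = TRUE)[[1]]
      if (length(path) == 1) spec[[path]] <- grid[i, col]
      else spec[[path[1]]][[path[2]]] <- grid[i, col]
    }
    out <- tryCatch(run_experiment(spec), error = function(e) e)
    if (inherits(out, "error"))
      return(data.frame(theta_power = NA, theta_freq = NA, gamma_power = NA,
                        gamma_freq = NA, n_none = NA, n_theta = NA,
                        n_gamma = NA, n_mixed = NA,
                        error = conditionMessage(out)))
    cm <- if (is.null(out$counts)) rep(NA, 4) else rowMeans(out$counts)
    data.frame(theta_power = out$theta$power, theta_freq = out$theta$freq,
               gamma_power = out$gamma$power, gamma_freq = out$gamma$freq,
               n_none = cm[1], n_theta = cm[2], n_gamma = cm[3],
               n_mixed = cm[4], error = NA_character_)
  })
  cbind(grid, do.call(rbind, res))
}

#' Named scenario registry
#'
#' Pre-configured specs (and scan templates) for the package's headline
#' scenarios: the 9-hotspot random map, single/double hotspot geometries
#' and the supplementary scans (homogeneous maps, rewiring, tau_z,
#' inhibitory sparsification, drive hotspots, ...). Scan-type entries
#' carry a `grid` attribute consumed by [run_scan()].
#'
#' @param name scenario name; see [scenario_names()]
#' @param seeds replicate seeds
#' @return `experiment_spec`, possibly with a `grid` attribute
#' @export
scenario_spec <- function(name, seeds = 1:4) {
  dbl <- function(r, d) list(kind = "double", d = d, radius = r)
  sngl <- function(r) list(kind = "single", radius = r)
  spec <- switch(name,
    fig2_random9 = experiment_spec(name, list(kind = "random", n = 9,
                                              radius = 4.2), seeds = seeds),
    fig3_radius_scan = {
      # wider-reach map parameterization so the scan covers radii up to ~7
      s <- experiment_spec(name, c(sngl(4.5), list(B = 0.02, R_amp = 12)),
                           seeds = seeds)
      attr(s, "grid") <- data.frame(map.radius = c(3.4, 4.5, 5.5, 6.2, 6.8))
      s
    },
    fig4F = experiment_spec(name, dbl(4.2, 4), seeds = seeds),
    fig4H = experiment_spec(name, dbl(6.1, 8), seeds = seeds),
    fig4_rd_grid = {
      s <- experiment_spec(name, dbl(4.2, 6), seeds = seeds)
      attr(s, "grid") <- expand.grid(map.radius = c(4.2, 5.4, 6.1),
                                     map.d = c(4, 6, 8))
      s
    },
    fig5_random6_large = experiment_spec(name, list(kind = "random", n = 6,
                                                    radius = 5.4), seeds = seeds),
    fig5_random6_small = experiment_spec(name, list(kind = "random", n = 6,
                                                    radius = 2.8), seeds = seeds),
    fig6_mi_line = experiment_spec(name, dbl(6.1, 8),
      analyses = c("rhythm", "mi"),
      mi_locations = rbind(c(6, 10), c(6, 12), c(6, 13), c(6, 14), c(6, 15),
                           c(6, 16), c(6, 17), c(6, 18), c(4, 19), c(0, 0)),
      seeds = seeds),
    s1_no_I_Mcurrent = experiment_spec(name,
      c(dbl(6.1, 8), list(I_gks_zero = TRUE)),
      topology = list(wII = 0.06, wIE = 0.035), seeds = seeds),
    s2_homogeneous = {
      s <- experiment_spec(name, list(kind = "uniform", value = 0.2),
                           seeds = seeds)
      attr(s, "grid") <- data.frame(map.value = seq(0, 1.5, by = 0.3))
      s
    },
    s4_lb_drive_grid = {
      s <- experiment_spec(name, sngl(5.6), seeds = seeds)
      attr(s, "grid") <- expand.grid(map.gks_min = c(0.0, 0.2, 0.4),
                                     drive.I_base = c(2.0, 3.0, 4.0))
      s
    },
    s6_s9_rewiring = {
      s <- experiment_spec(name, sngl(5.7), seeds = seeds)
      attr(s, "grid") <- data.frame(topology.rewire_p = c(0, 0.1, 0.3, 0.875))
      s
    },
    s7_tauz = {
      s <- experiment_spec(name, dbl(6.1, 8), seeds = seeds)
      attr(s, "grid") <- data.frame(tau_z = c(25, 50, 75, 100, 125))
      s
    },
    s10_drive_hotspots = {
      s <- experiment_spec(name, list(kind = "uniform", value = 0.2),
        drive = list(I_base = 3.0, hotspots = .double_sites(8),
                     hotspot_radius = 3, I_target = 4.5), seeds = seeds)
      attr(s, "grid") <- data.frame(map.value = c(0.2, 0.6, 1.0, 1.4))
      s
    },
    s14_drive_tauI = {
      s <- experiment_spec(name, dbl(6.1, 8), seeds = seeds)
      tau <- c(2, 3, 4.5)
      attr(s, "grid") <- data.frame(topology.tau_inh = tau,
                                    topology.wII = 0.04 * 3 / tau,
                                    topology.wIE = 0.04 * 3 / tau)
      s
    },
    s15_sparse_inhibition = {
      s <- experiment_spec(name, dbl(6.1, 8), seeds = seeds)
      attr(s, "grid") <- data.frame(
        topology.inh_density = c(1, 0.8, 0.6, 0.4),
        topology.inh_w = c(0.04, 0.045, 0.048, 0.075))
      s
    },
    stop("unknown scenario: ", name))
  spec
}

#' @rdname scenario_spec
#' @export
scenario_names <- function() {
  c("fig2_random9", "fig3_radius_scan", "fig4F", "fig4H", "fig4_rd_grid",
    "fig5_random6_large", "fig5_random6_small", "fig6_mi_line",
    "s1_no_I_Mcurrent", "s2_homogeneous", "s4_lb_drive_grid",
    "s6_s9_rewiring", "s7_tauz", "s10_drive_hotspots", "s14_drive_tauI",
    "s15_sparse_inhibition")
}
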