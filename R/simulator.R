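#' External drive configuration
#'
#' A constant current is applied to every excitatory cell (external or
#' feed-forward input targets the pyramidal population; interneurons are
#' recruited synaptically, the PING arrangement). An optional E-cell
#' subset (an external "stimulus") receives a different drive, and
#' `I_base_I` can add a direct drive to the I population.
#'
#' @param I_base constant drive per E cell (uA/cm^2)
#' @param target_ids optional integer IDs of targeted E cells
#' @param I_target drive applied to the targeted cells (uA/cm^2)
#' @param I_base_I constant drive per I cell (uA/cm^2)
#' @return object of class `drive_config`
#' @export
drive_config <- function(I_base = 3.0, target_ids = NULL, I_target = NULL,
                         I_base_I = 0) {
  stopifnot(is.finite(I_base), is.finite(I_base_I))
  if (!is.null(target_ids)) stopifnot(is.finite(I_target))
  structure(list(I_base = I_base, target_ids = target_ids,
                 I_target = I_target, I_base_I = I_base_I),
            class = "drive_config")
}

#' Poisson current-pulse noise configuration
#'
#' Per-cell independent Poisson trains of square current pulses;
#' overlapping pulses sum. Disabled by default.
#'
#' @param enabled logical
#' @param rate Poisson rate per cell (1/ms)
#' @param amp pulse amplitude (uA/cm^2)
#' @param width pulse duration (ms)
#' @return object of class `noise_config`
#' @export
noise_config <- function(enabled = FALSE, rate = 1 / 150, amp = 6, width = 1) {
  stopifnot(rate >= 0, amp >= 0, width >= 0)
  structure(list(enabled = enabled, rate = rate, amp = amp, width = width),
            class = "noise_config")
}

#' Simulation configuration
#'
#' @param dt integration step (ms), at most 0.1
#' @param duration total simulated time (ms)
#' @param transient initial span (ms) that analyses discard
#' @param record_ids cell IDs whose voltage (and, optionally, synaptic
#'   conductances) are recorded, or NULL
#' @param record_every voltage sampling interval (ms)
#' @param record_syn also record the synaptic conductance accumulators
#' @return object of class `sim_config`
#' @export
sim_config <- function(dt = 0.05, duration = 5500, transient = 500,
                       record_ids = NULL, record_every = 1,
                       record_syn = FALSE) {
  stopifnot(dt > 0, dt <= 0.1, duration > transient, transient >= 0)
  structure(list(dt = dt, duration = duration, transient = transient,
                 record_ids = record_ids, record_every = record_every,
                 record_syn = record_syn), class = "sim_config")
}

#' Simulate the full E-I network
#'
#' Integrates every cell's Hodgkin-Huxley dynamics (per-cell gKs taken from
#' the map) coupled by exponential-decay conductance synapses, under
#' constant external drive and optional Poisson pulse noise. Initial
#' voltages are drawn uniformly in \[-70, -55\] mV with gates at steady
#' state, independently per cell from the seed; identical configuration
#' and seed give a bit-identical spike raster.
#'
#' @param topo [build_topology()] result (its `syn` slot supplies the
#'   synaptic parameters)
#' @param map [generate_gks_map()] / [uniform_gks_map()] result, or a
#'   numeric vector of per-cell gKs values
#' @param drive [drive_config()]
#' @param noise [noise_config()]
#' @param cfg [sim_config()]
#' @param params [neuron_params()]
#' @param seed integer RNG seed
#' @return object of class `spike_raster`: data.frame-backed list with
#'   `events` (`time` ms, `id`), `duration`, `transient`, `n_E`, `n_I`, and
#'   optional `voltages` / `ge` / `gi` matrices with `rec_times`
#' @export
run_simulation <- function(topo, map, drive = drive_config(),
                           noise = noise_config(), cfg = sim_config(),
                           params = neuron_params(), seed = 1L) {
  n <- length(topo$kind)
  gks <- if (inherits(map, "gks_map")) .gks_vector(map) else as.numeric(map)
  if (length(gks) != n)
    stop("gKs map size (", length(gks), ") does not match network size (", n, ")")
  if (any(!is.finite(gks)) || any(gks < 0) || any(gks > 1.5))
    stop("per-cell gKs values must lie in [0, 1.5] mS/cm^2")
  is_exc <- as.integer(topo$kind == "E")

  ed <- topo$edges[order(topo$edges$src), ]
  deg <- tabulate(ed$src, nbins = n)
  edge_ptr <- c(0L, cumsum(deg))
  idrive <- ifelse(topo$kind == "E", drive$I_base,
                   if (is.null(drive$I_base_I)) 0 else drive$I_base_I)
  if (!is.null(drive$target_ids)) {
    if (any(topo$kind[drive$target_ids] != "E"))
      stop("target_ids must be E cells")
    idrive[drive$target_ids] <- drive$I_target
  }

  set.seed(seed)
  v0 <- stats::runif(n, -70, -55)
  rec_ids <- if (is.null(cfg$record_ids)) integer(0) else
    as.integer(cfg$record_ids) - 1L

  res <- .sim_network_cpp(
    n_cells = n, is_exc = is_exc, gks = gks,
    edge_ptr = edge_ptr, edge_tgt = as.integer(ed$tgt) - 1L,
    edge_w = as.numeric(ed$w), idrive = idrive,
    noise_on = isTRUE(noise$enabled), noise_rate = noise$rate,
    noise_amp = noise$amp, noise_width = noise$width,
    tau_e = topo$syn$tau_exc, tau_i = topo$syn$tau_inh,
    e_exc = topo$syn$E_exc, e_inh = topo$syn$E_inh,
    params = .params_vec(params), dt = cfg$dt, duration = cfg$duration,
    lockout_ms = 2, v0 = v0, record_ids = rec_ids,
    record_every = if (length(rec_ids)) cfg$record_every else 0,
    record_syn = isTRUE(cfg$record_syn))

  out <- list(events = data.frame(time = res$spike_time, id = res$spike_id),
              duration = cfg$duration, transient = cfg$transient,
              n_E = sum(is_exc), n_I = n - sum(is_exc), seed = seed)
  if (length(rec_ids)) {
    out$rec_times <- res$rec_times
    out$voltages <- res$voltages
    colnames(out$voltages) <- as.character(cfg$record_ids)
    if (isTRUE(cfg$record_syn)) { out$ge <- res$ge; out$gi <- res$gi }
  }
  structure(out, class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike raster: %d events, %d cells (%d E + %d I), %.0f ms\n",
              nrow(x$events), x$n_E + x$n_I, x$n_E, x$n_I, x$duration))
  invisible(x)
}

#' Write / read a spike raster as two-column delimited text
#'
#' @param raster `spike_raster`
#' @param path output file
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# achnet raster duration=%g transient=%g n_E=%d n_I=%d",
                     raster$duration, raster$transient, raster$n_E,
                     raster$n_I), con)
  writeLines("time_ms\tneuron_ID", con)
  utils::write.table(raster$events, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- strsplit(sub("^# achnet raster ", "", readLines(path, n = 1)), " ")[[1]]
  kv <- do.call(rbind, strsplit(hdr, "="))
  val <- as.numeric(kv[, 2]); names(val) <- kv[, 1]
  ev <- utils::read.table(path, skip = 2, col.names = c("time", "id"))
  structure(list(events = ev, duration = val[["duration"]],
                 transient = val[["transient"]], n_E = as.integer(val[["n_E"]]),
                 n_I = as.integer(val[["n_I"]])), class = "spike_raster")
}

#' Stimulus-gating experiment
#'
#' Measures how a gKs hotspot gates the response of E cells targeted by an
#' external current step, under three conditions: (1) targets inside the
#' hotspot, (2) targets outside the hotspot, (3) homogeneous map at the
#' default gKs with the same targets (no-modulation baseline). Returns the
#' mean firing rate of the targeted set in each condition and the relative
#' change of (1) and (2) versus (3).
#'
#' @param map_kind `"single"` or `"double"` hotspot map
#' @param radius hotspot radius (lattice units)
#' @param I_target stimulus drive to targeted cells (uA/cm^2)
#' @param n_target number of targeted E cells (nearest to the probe point)
#' @param seed integer RNG seed
#' @param cfg [sim_config()]
#' @param homog_gks gKs of the homogeneous baseline map (mS/cm^2)
#' @return list with per-condition rates (Hz) and `rel_inside`,
#'   `rel_outside` relative changes
#' @export
stimulus_experiment <- function(map_kind = c("single", "double"),
                                radius = 4.6, I_target = 4.5,
                                n_target = 12, seed = 1L,
                                cfg = sim_config(duration = 3000),
                                homog_gks = 1.5) {
  map_kind <- match.arg(map_kind)
  geom <- lattice_geometry()
  sites <- if (map_kind == "single") cbind(10L, 10L) else
    rbind(c(6L, 10L), c(14L, 10L))
  map <- generate_gks_map(sites, target_radius = radius)
  topo <- build_topology(geom)

  inside_pt <- sites[1, ]
  # a point maximally far from all hotspot centers
  outside_pt <- if (map_kind == "single") (sites[1, ] + 10L) %% 20L else
    c((sites[1, 1] + 10L) %% 20L, (sites[1, 2] + 10L) %% 20L)
  pick_targets <- function(pt) {
    d <- periodic_distance(topo$positions[seq_len(geom$n_E), ],
                           matrix(pt, 1), geom$L_E)
    order(d)[seq_len(n_target)]
  }
  rate_of <- function(map_use, ids) {
    r <- run_simulation(topo, map_use,
                        drive = drive_config(3.0, ids, I_target),
                        noise = noise_config(enabled = TRUE),
                        cfg = cfg, seed = seed)
    ev <- r$events
    n_sp <- sum(ev$id %in% ids & ev$time > cfg$transient)
    1000 * n_sp / length(ids) / (cfg$duration - cfg$transient)
  }
  ids_in <- pick_targets(inside_pt)
  ids_out <- pick_targets(outside_pt)
  homog <- uniform_gks_map(homog_gks)
  r1 <- rate_of(map, ids_in)
  r2 <- rate_of(map, ids_out)
  r3_in <- rate_of(homog, ids_in)
  r3_out <- rate_of(homog, ids_out)
  list(rate_inside = r1, rate_outside = r2,
       rate_baseline_inside = r3_in, rate_baseline_outside = r3_out,
       rel_inside = (r1 - r3_in) / r3_in,
       rel_outside = (r2 - r3_out) / r3_out)
}
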