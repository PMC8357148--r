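#' Continuous spike trace by Gaussian convolution
#'
#' Each spike contributes a unit-area Gaussian (sigma = 1.5 ms by default)
#' evaluated on a uniform time grid, converting the discrete train into a
#' continuous rate proxy.
#'
#' @param spike_times spike times (ms)
#' @param grid uniform time grid (ms)
#' @param sigma Gaussian width (ms)
#' @return numeric trace on `grid` (1/ms units; integrates to the spike
#'   count up to boundary truncation)
#' @export
spike_trace <- function(spike_times, grid, sigma = 1.5) {
  stopifnot(sigma > 0)
  out <- numeric(length(grid))
  if (length(spike_times) == 0) return(out)
  dt <- grid[2] - grid[1]
  half <- 6 * sigma
  for (ts in spike_times) {
    i0 <- max(1L, ceiling((ts - half - grid[1]) / dt) + 1L)
    i1 <- min(length(grid), floor((ts + half - grid[1]) / dt) + 1L)
    if (i0 <= i1) {
      idx <- i0:i1
      out[idx] <- out[idx] + stats::dnorm(grid[idx], ts, sigma)
    }
  }
  out
}

# IDs of the k E cells nearest to a lattice location (periodic metric,
# ties broken as in the topology: distance, |angle to +x|, ID)
.nearest_E <- function(location, k, geom = lattice_geometry()) {
  ex <- rep(0:(geom$L_E - 1), each = geom$L_E)
  ey <- rep(0:(geom$L_E - 1), times = geom$L_E)
  dx <- .wrap(ex - location[1], geom$L_E)
  dy <- .wrap(ey - location[2], geom$L_E)
  order(dx^2 + dy^2, abs(atan2(dy, dx)))[seq_len(k)]
}

#' Local field potential proxy at a lattice location
#'
#' Sums the Gaussian-smoothed spike traces (spike mode) or the recorded
#' membrane voltages (voltage mode) of the `k` E cells nearest to the
#' location under the periodic metric. The spike-derived proxy uses the 12
#' closest cells by default.
#'
#' @param raster `spike_raster`; voltage mode requires it to carry
#'   recorded voltages for the contributing cells
#' @param location lattice point `c(x, y)` (E-lattice units)
#' @param k number of contributing E cells
#' @param mode `"spike"` or `"voltage"`
#' @param sample_every sampling interval of the trace (ms)
#' @param sigma Gaussian width for spike mode (ms)
#' @param geom [lattice_geometry()]
#' @return object of class `lfp_trace`: list with `times`, `samples`,
#'   `location`, `cell_ids`, `mode`
#' @export
lfp_at <- function(raster, location, k = 12, mode = c("spike", "voltage"),
                   sample_every = 1, sigma = 1.5,
                   geom = lattice_geometry()) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, k <= geom$n_E)
  ids <- .nearest_E(location, k, geom)
  if (mode == "spike") {
    grid <- seq(raster$transient, raster$duration, by = sample_every)
    ev <- raster$events
    st <- ev$time[ev$id %in% ids]
    samples <- spike_trace(st, grid, sigma)
  } else {
    if (is.null(raster$voltages))
      stop("voltage mode requires recorded voltages")
    have <- match(as.character(ids), colnames(raster$voltages))
    if (anyNA(have))
      stop("voltages were not recorded for all contributing cells")
    keep <- raster$rec_times >= raster$transient
    grid <- raster$rec_times[keep]
    samples <- rowSums(raster$voltages[keep, have, drop = FALSE])
  }
  structure(list(times = grid, samples = samples, location = location,
                 cell_ids = ids, mode = mode), class = "lfp_trace")
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (order 3) applied forward and backward
#' (`signal::filtfilt`), so the pass band is amplitude-preserving and
#' phase-free. The band is usually centered on the measured network peak
#' frequency: theta peak +/- 2 Hz, gamma peak +/- 10 Hz.
#'
#' @param x numeric trace or `lfp_trace`
#' @param band numeric `c(lo, hi)` pass band (Hz)
#' @param fs sampling rate (Hz); taken from an `lfp_trace` input
#' @return filtered numeric trace (same length)
#' @export
band_filter <- function(x, band, fs = 1000) {
  if (inherits(x, "lfp_trace")) {
    fs <- 1000 / (x$times[2] - x$times[1])
    x <- x$samples
  }
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            band[2] < fs / 2)
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of the analytic signal; `Mod()` of the result is the
#' amplitude envelope and `Arg()` the instantaneous phase.
#'
#' @param x real numeric vector
#' @return complex vector of the same length
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Entropy-based modulation index of phase-amplitude coupling
#'
#' The instantaneous theta phase (analytic signal of the theta-filtered
#' trace) is divided into `n_bins` bins; the mean gamma amplitude envelope
#' per bin, normalized to a distribution P, gives
#' `MI = (log N - H(P)) / log N` with `H` the Shannon entropy. MI is 0 for
#' an amplitude uniform across phases and 1 when all amplitude concentrates
#' in a single bin.
#'
#' @param theta_trace theta-band filtered trace
#' @param gamma_trace gamma-band filtered trace (same length)
#' @param n_bins number of phase bins (18 = 20-degree bins)
#' @param edge_discard samples dropped at each end after the Hilbert
#'   transform (end-effect guard); with 1-ms sampling the default drops
#'   200 ms
#' @return MI in `[0, 1]`; `NA` with a warning when the envelope is all
#'   zero
#' @export
modulation_index <- function(theta_trace, gamma_trace, n_bins = 18,
                             edge_discard = 200) {
  stopifnot(length(theta_trace) == length(gamma_trace), n_bins >= 2)
  phase <- Arg(analytic_signal(theta_trace))
  amp <- Mod(analytic_signal(gamma_trace))
  n <- length(phase)
  if (2 * edge_discard >= n) stop("trace too short for the edge discard")
  keep <- (edge_discard + 1):(n - edge_discard)
  phase <- phase[keep]; amp <- amp[keep]
  if (all(amp == 0)) {
    warning("all-zero gamma envelope: MI undefined")
    return(NA_real_)
  }
  .mi_entropy(phase, amp, n_bins)
}

# entropy core of the modulation index: phase-binned mean amplitude,
# normalized, Kullback-Leibler distance to uniform over log N
.mi_entropy <- function(phase, amp, n_bins) {
  bins <- pmin(floor((phase + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  mean_amp <- vapply(seq_len(n_bins), function(b) {
    v <- amp[bins == b]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  P <- mean_amp / sum(mean_amp)
  H <- -sum(ifelse(P > 0, P * log(P), 0))
  (log(n_bins) - H) / log(n_bins)
}

#' Theta-gamma coupling strength along a line of locations
#'
#' For each location, builds the spike-derived (or voltage-derived) LFP
#' proxy, filters it around the network theta and gamma peak frequencies
#' and computes the modulation index, together with the location's distance
#' from the nearest hotspot center.
#'
#' @param raster `spike_raster` (or list of replicate rasters, averaged)
#' @param centers matrix of hotspot-center coordinates (rows)
#' @param locations matrix of probe locations (rows, E-lattice units)
#' @param theta_halfwidth,gamma_halfwidth filter half-widths (Hz)
#' @param k contributing E cells per location
#' @param mode `"spike"` or `"voltage"`
#' @param geom [lattice_geometry()]
#' @return data.frame with `x`, `y`, `distance` and `mi` (replicate mean)
#' @export
mi_distance_profile <- function(raster, centers, locations,
                                theta_halfwidth = 2, gamma_halfwidth = 10,
                                k = 12, mode = "spike",
                                geom = lattice_geometry()) {
  rasters <- if (inherits(raster, "spike_raster")) list(raster) else raster
  locations <- matrix(locations, ncol = 2)
  centers <- matrix(centers, ncol = 2)
  mi_mat <- sapply(rasters, function(r) {
    sp <- network_spectrum(r, "E")
    f_th <- band_peak(sp, c(2.5, 20))$freq
    f_ga <- band_peak(sp, c(25, 100))$freq
    th_band <- c(max(0.5, f_th - theta_halfwidth), f_th + theta_halfwidth)
    ga_band <- c(f_ga - gamma_halfwidth, f_ga + gamma_halfwidth)
    apply(locations, 1, function(loc) {
      lfp <- lfp_at(r, loc, k = k, mode = mode, geom = geom)
      modulation_index(band_filter(lfp, th_band),
                       band_filter(lfp, ga_band))
    })
  })
  mi_mat <- matrix(mi_mat, nrow = nrow(locations))
  dist <- apply(locations, 1, function(loc)
    min(periodic_distance(matrix(loc, 1), centers, geom$L_E)))
  data.frame(x = locations[, 1], y = locations[, 2], distance = dist,
             mi = rowMeans(mi_mat, na.rm = TRUE))
}
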