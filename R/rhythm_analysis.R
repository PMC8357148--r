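#' @importFrom stats mvfft fft
NULL

# bin spike times into 1-ms counts over (transient, duration]
.bin_counts <- function(times, ids, n_cells, duration, transient,
                        bin = 1) {
  keep <- times > transient & times <= duration
  n_bins <- floor((duration - transient) / bin)
  b <- pmin(floor((times[keep] - transient) / bin) + 1L, n_bins)
  lin <- (ids[keep] - 1L) * n_bins + b
  counts <- tabulate(lin, nbins = n_bins * n_cells)
  dim(counts) <- c(n_bins, n_cells)
  counts
}

# truncated Gaussian smoothing kernel applied column-wise (unit sum)
.smooth_cols <- function(m, sigma, bin = 1) {
  if (is.null(sigma) || sigma <= 0) return(m)
  half <- ceiling(3 * sigma / bin)
  k <- stats::dnorm(seq(-half, half) * bin, sd = sigma)
  k <- k / sum(k)
  out <- stats::filter(m, k, sides = 2)
  out[is.na(out)] <- 0
  matrix(out, nrow(m), ncol(m))
}

# Correlogram-based power spectra, one per column of the count matrix:
# mean-subtracted autocovariance up to max_lag, Hann-windowed, magnitude of
# its DFT on an nfft grid. Sampling rate = 1/bin kHz.
.acf_spectrum <- function(counts, bin = 1, max_lag = 1024, nfft = 4096) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  m <- min(max_lag, n - 1)
  x <- sweep(counts, 2, colMeans(counts))
  pad <- 2^ceiling(log2(n + m + 1))
  out <- matrix(0, nfft %/% 2 + 1, ncol(counts))
  hann <- 0.5 * (1 + cos(pi * seq(-m, m) / m))
  chunk <- 64L
  for (j0 in seq(1, ncol(counts), by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, ncol(counts))
    X <- mvfft(rbind(x[, jj, drop = FALSE],
                     matrix(0, pad - n, length(jj))))
    ac <- Re(mvfft(Mod(X)^2 + 0i, inverse = TRUE)) / pad / n
    r <- ac[seq_len(m + 1), , drop = FALSE]
    sym <- rbind(r[(m + 1):2, , drop = FALSE], r) * hann
    SP <- mvfft(rbind(sym, matrix(0, nfft - nrow(sym), length(jj))))
    out[, jj] <- Mod(SP[seq_len(nfft %/% 2 + 1), , drop = FALSE])
  }
  fs <- 1000 / bin
  list(frequencies = seq(0, nfft %/% 2) * fs / nfft, power = out)
}

#' Network power spectrum from a spike raster
#'
#' The raster correlogram of the chosen population, Fourier transformed.
#' In the default `"cells"` mode the correlogram counts same-neuron spike
#' pairs (the sum of the per-cell spike-train autocorrelations), so
#' rhythms expressed by individual cells survive even when subpopulations
#' oscillate in anti-phase and cancel in the pooled rate; in
#' `"population"` mode it is the autocorrelation of the pooled spike-count
#' histogram. Either way the mean-subtracted autocorrelation is
#' Hann-windowed and its magnitude spectrum returned on a grid finer than
#' 0.25 Hz.
#'
#' @param raster `spike_raster` (from [run_simulation()])
#' @param population `"E"`, `"I"` or `"all"`
#' @param bin histogram bin (ms)
#' @param correlogram `"cells"` (same-neuron pairs; default) or
#'   `"population"` (pooled histogram)
#' @return object of class `power_spectrum`: list with `frequencies` (Hz),
#'   `power`, and a `silent` flag for empty rasters
#' @export
network_spectrum <- function(raster, population = c("E", "I", "all"),
                             bin = 1,
                             correlogram = c("cells", "population")) {
  population <- match.arg(population)
  correlogram <- match.arg(correlogram)
  ev <- raster$events
  keep <- switch(population,
                 E = ev$id <= raster$n_E,
                 I = ev$id > raster$n_E,
                 all = rep(TRUE, nrow(ev)))
  ev <- ev[keep & ev$time > raster$transient, ]
  if (nrow(ev) == 0) {
    nfft <- 4096
    return(structure(list(frequencies = seq(0, nfft %/% 2) * (1000 / bin) / nfft,
                          power = rep(0, nfft %/% 2 + 1), silent = TRUE),
                     class = "power_spectrum"))
  }
  n_all <- raster$n_E + raster$n_I
  if (correlogram == "population") {
    counts <- .bin_counts(ev$time, rep(1L, nrow(ev)), 1L, raster$duration,
                          raster$transient, bin)
    sp <- .acf_spectrum(counts, bin = bin)
    power <- drop(sp$power)
  } else {
    counts <- .bin_counts(ev$time, ev$id, n_all, raster$duration,
                          raster$transient, bin)
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    sp <- .acf_spectrum(counts, bin = bin)
    power <- rowSums(sp$power)
  }
  structure(list(frequencies = sp$frequencies, power = power,
                 silent = FALSE), class = "power_spectrum")
}

#' Average power spectra across replicate runs
#'
#' @param spectra list of `power_spectrum` objects on a common grid
#' @return `power_spectrum` with element-wise mean power
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  p <- Reduce(`+`, lapply(spectra, `[[`, "power")) / length(spectra)
  structure(list(frequencies = spectra[[1]]$frequencies, power = p,
                 silent = all(vapply(spectra, `[[`, TRUE, "silent"))),
            class = "power_spectrum")
}

#' Peak frequency and power within a band
#'
#' @param spectrum `power_spectrum`
#' @param band numeric length-2 frequency interval (Hz); the theta search
#'   band is 2.5-20 Hz and the gamma search band 25-100 Hz
#' @return list with `freq` (Hz) and `power`
#' @export
band_peak <- function(spectrum, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  inb <- spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2]
  if (!any(inb)) stop("band outside spectrum support")
  i <- which.max(spectrum$power[inb])
  list(freq = spectrum$frequencies[inb][i], power = spectrum$power[inb][i])
}

#' Is a band peak significant?
#'
#' A band carries a rhythm when its peak power exceeds `threshold_factor`
#' times the mean power over the full analyzed range (2-100 Hz); one rule
#' shared by cells and network.
#'
#' @inheritParams band_peak
#' @param threshold_factor multiple of the mean power
#' @param full_range analyzed range (Hz)
#' @return logical
#' @export
band_significant <- function(spectrum, band, threshold_factor = 4,
                             full_range = c(2, 100)) {
  base <- spectrum$frequencies >= full_range[1] &
    spectrum$frequencies <= full_range[2]
  mp <- mean(spectrum$power[base])
  if (mp == 0) return(FALSE)
  band_peak(spectrum, band)$power > threshold_factor * mp
}

#' Classify the rhythmicity of individual E cells
#'
#' Per-cell spike trains are binned at 1 ms, smoothed with a small Gaussian
#' kernel (to keep harmonics of slow periodic firing from leaking into the
#' gamma band), and the autocorrelation spectrum of each is compared to its
#' own mean power over 2-100 Hz: a band is flagged when its peak exceeds
#' `threshold_factor` times that mean. Labels: `none` (no flag or fewer
#' than `min_spikes` spikes), `theta`, `gamma`, `mixed` (both).
#'
#' @param raster `spike_raster`
#' @param theta_band,gamma_band search bands (Hz)
#' @param threshold_factor multiple of the mean power that a peak must exceed
#' @param smooth_sigma Gaussian smoothing sigma (ms)
#' @param min_spikes minimum post-transient spike count for classification
#' @param cv_metronome ISI coefficient-of-variation below which a train is
#'   treated as metronomic: such a train carries exactly one rhythm (its
#'   firing rate), and spectral content at harmonics of that rate in the
#'   other band is discounted
#' @return factor vector of length `n_E` with levels
#'   `none, theta, gamma, mixed`, ordered by cell ID
#' @export
classify_cells <- function(raster, theta_band = c(2.5, 20),
                           gamma_band = c(25, 100), threshold_factor = 4,
                           smooth_sigma = 3, min_spikes = 5,
                           cv_metronome = 0.2) {
  ev <- raster$events
  ev <- ev[ev$id <= raster$n_E & ev$time > raster$transient, ]
  counts <- .bin_counts(ev$time, ev$id, raster$n_E, raster$duration,
                        raster$transient)
  n_sp <- colSums(counts)
  sm <- .smooth_cols(counts, smooth_sigma)
  sp <- .acf_spectrum(sm)
  fr <- sp$frequencies
  base <- fr >= 2 & fr <= 100
  mp <- colMeans(sp$power[base, , drop = FALSE])
  pk <- function(band) {
    inb <- fr >= band[1] & fr <= band[2]
    apply(sp$power[inb, , drop = FALSE], 2, max)
  }
  th <- pk(theta_band) > threshold_factor * mp & mp > 0
  ga <- pk(gamma_band) > threshold_factor * mp & mp > 0

  # metronomic trains (near-zero ISI variability) express one rhythm: their
  # firing rate; power in the other band is harmonic leakage, not a rhythm
  both <- which(th & ga & n_sp >= min_spikes)
  for (i in both) {
    st <- ev$time[ev$id == i]
    if (length(st) < 3) next
    isi <- diff(sort(st))
    if (stats::sd(isi) / mean(isi) < cv_metronome) {
      f0 <- 1000 / mean(isi)
      th[i] <- f0 >= theta_band[1] && f0 <= theta_band[2]
      ga[i] <- f0 >= gamma_band[1] && f0 <= gamma_band[2]
    }
  }
  lab <- ifelse(n_sp < min_spikes, "none",
                ifelse(th & ga, "mixed",
                       ifelse(th, "theta", ifelse(ga, "gamma", "none"))))
  factor(lab, levels = c("none", "theta", "gamma", "mixed"))
}

#' Classify a single spike train
#'
#' @param spike_times spike times (ms)
#' @param duration analyzed span end (ms)
#' @param transient analyzed span start (ms)
#' @param ... passed to [classify_cells()]
#' @return label factor of length 1
#' @export
classify_train <- function(spike_times, duration, transient = 0, ...) {
  raster <- structure(list(events = data.frame(
    time = spike_times, id = rep(1L, length(spike_times))),
    duration = duration, transient = transient, n_E = 1L, n_I = 0L),
    class = "spike_raster")
  classify_cells(raster, ...)[1]
}

#' Per-cell rhythm report for one simulation
#'
#' Bundles the per-E-cell classification with the network-level band
#' diagnostics: theta/gamma peak frequencies and powers (search bands
#' 2.5-20 and 25-100 Hz) and the per-label cell counts.
#'
#' @inheritParams classify_cells
#' @return list with `labels`, `counts`, `theta_freq`, `theta_power`,
#'   `gamma_freq`, `gamma_power`, `theta_significant`, `gamma_significant`
#' @export
rhythm_report <- function(raster, theta_band = c(2.5, 20),
                          gamma_band = c(25, 100), threshold_factor = 4) {
  labels <- classify_cells(raster, theta_band, gamma_band, threshold_factor)
  sp <- network_spectrum(raster, "E")
  th <- band_peak(sp, theta_band)
  ga <- band_peak(sp, gamma_band)
  list(labels = labels, counts = table(labels),
       theta_freq = th$freq, theta_power = th$power,
       gamma_freq = ga$freq, gamma_power = ga$power,
       theta_significant = band_significant(sp, theta_band, threshold_factor),
       gamma_significant = band_significant(sp, gamma_band, threshold_factor),
       spectrum = sp)
}

#' Mean firing rate of each E cell on the lattice
#'
#' @param raster `spike_raster`
#' @param window optional `c(from, to)` time window (ms); defaults to the
#'   post-transient span (windowed snapshots give short-time rate maps)
#' @param geom [lattice_geometry()]
#' @return L_E x L_E matrix of rates (Hz), indexed `[x+1, y+1]`
#' @export
firing_rate_map <- function(raster, window = NULL,
                            geom = lattice_geometry()) {
  if (is.null(window)) window <- c(raster$transient, raster$duration)
  ev <- raster$events
  ev <- ev[ev$id <= raster$n_E & ev$time > window[1] & ev$time <= window[2], ]
  cnt <- tabulate(ev$id, nbins = raster$n_E)
  rate <- 1000 * cnt / diff(window)
  matrix(rate, geom$L_E, geom$L_E, byrow = TRUE)  # ID index = y + x*L
}

#' Mean and relative standard error across replicates
#'
#' @param values per-replicate measurements (e.g. band powers)
#' @return list with `mean`, `se` and `rse` (= se / |mean|; `NA` with a
#'   warning when the mean is 0)
#' @export
variability_stats <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(length(values))
  if (m == 0) {
    warning("mean is zero: RSE undefined")
    return(list(mean = m, se = se, rse = NA_real_))
  }
  list(mean = m, se = se, rse = se / abs(m))
}
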