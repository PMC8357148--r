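#' Biophysical parameters of the adapting cortical neuron model
#'
#' Hodgkin-Huxley type pyramidal-cell model with a fast inward Na+ current,
#' a delayed-rectifier K+ current, a leak current and a slow, low-threshold,
#' muscarine-sensitive K+ (M-type) adaptation current whose maximal
#' conductance `gKs` is supplied externally (it encodes the local level of
#' cholinergic modulation: 1.5 mS/cm^2 = no ACh, 0 = full blockade).
#'
#' @param C membrane capacitance (uF/cm^2)
#' @param gNa,gKdr,gL maximal conductances (mS/cm^2)
#' @param VNa,VK,VL reversal potentials (mV)
#' @param tau_z M-current activation time constant (ms)
#' @return object of class `neuron_params`
#' @export
neuron_params <- function(C = 1, gNa = 24.0, gKdr = 3.0, gL = 0.02,
                          VNa = 55.0, VK = -90.0, VL = -60.0, tau_z = 75) {
  stopifnot(C > 0, gNa >= 0, gKdr >= 0, gL >= 0, tau_z > 0)
  structure(list(C = C, gNa = gNa, gKdr = gKdr, gL = gL,
                 VNa = VNa, VK = VK, VL = VL, tau_z = tau_z),
            class = "neuron_params")
}

# parameter vector in the layout the C++ kernel expects
.params_vec <- function(p) {
  c(p$C, p$gNa, p$gKdr, p$gL, p$VNa, p$VK, p$VL, p$tau_z)
}

#' Steady-state gating functions
#'
#' Voltage dependence of the instantaneous Na+ activation `m_inf`, Na+
#' inactivation `h_inf`, delayed-rectifier activation `n_inf` and M-current
#' activation `z_inf`. Half-(in)activation voltages are -30 mV (m, n),
#' -40.5 mV (h) and -39 mV (z).
#'
#' @param V membrane potential (mV), vectorized
#' @return list with components `m_inf`, `h_inf`, `n_inf`, `z_inf`
#' @export
steady_state_gates <- function(V) {
  if (!all(is.finite(V))) stop("V must be finite")
  list(m_inf = 1 / (1 + exp((-V - 30.0) / 9.5)),
       h_inf = 1 / (1 + exp((V + 40.5) / 6.0)),
       n_inf = 1 / (1 + exp((-V - 30.0) / 10.0)),
       z_inf = 1 / (1 + exp((-V - 39.0) / 5.0)))
}

#' Voltage-dependent gate time constants
#'
#' @param V membrane potential (mV), vectorized
#' @return list with components `tau_h`, `tau_n` (ms)
#' @export
gate_time_constants <- function(V) {
  if (!all(is.finite(V))) stop("V must be finite")
  list(tau_h = 0.37 + 2.78 / (1 + exp((V + 40.5) / 6.0)),
       tau_n = 0.37 + 1.85 / (1 + exp((V + 27.0) / 15.0)))
}

#' Right-hand side of the single-neuron ODE system
#'
#' Current balance: `C dV/dt = -INa - IKdr - IKs - IL + I_ext - I_syn`, with
#' `INa = gNa m_inf^3 h (V - VNa)`, `IKdr = gKdr n^4 (V - VK)`,
#' `IKs = gKs z (V - VK)`, `IL = gL (V - VL)`. Gates follow first-order
#' relaxation to their steady states.
#'
#' @param state numeric vector or list with named components `V`, `h`, `n`, `z`
#' @param params [neuron_params()]
#' @param gKs M-current maximal conductance (mS/cm^2), must lie in the
#'   modulation range `[0, 1.5]`
#' @param I_ext external current (uA/cm^2)
#' @param I_syn synaptic current (uA/cm^2), positive = hyperpolarizing
#' @return named numeric vector `c(dV, dh, dn, dz)` in mV/ms and 1/ms
#' @export
hh_derivatives <- function(state, params = neuron_params(), gKs, I_ext = 0,
                           I_syn = 0) {
  if (!is.finite(gKs) || gKs < 0 || gKs > 1.5)
    stop("gKs must lie in [0, 1.5] mS/cm^2")
  s <- as.list(state)
  eps <- 1e-3  # tolerate integrator round-off at the gate bounds
  stopifnot(s$h >= -eps, s$h <= 1 + eps, s$n >= -eps, s$n <= 1 + eps,
            s$z >= -eps, s$z <= 1 + eps)
  g <- steady_state_gates(s$V)
  tc <- gate_time_constants(s$V)
  INa  <- params$gNa * g$m_inf^3 * s$h * (s$V - params$VNa)
  IKdr <- params$gKdr * s$n^4 * (s$V - params$VK)
  IKs  <- gKs * s$z * (s$V - params$VK)
  IL   <- params$gL * (s$V - params$VL)
  c(dV = (-INa - IKdr - IKs - IL + I_ext - I_syn) / params$C,
    dh = (g$h_inf - s$h) / tc$tau_h,
    dn = (g$n_inf - s$n) / tc$tau_n,
    dz = (g$z_inf - s$z) / params$tau_z)
}

#' Resting state of the neuron by root-solving
#'
#' Finds the quiescent fixed point (all gates at steady state, `dV/dt = 0`)
#' for a given `gKs` and external current.
#'
#' @inheritParams hh_derivatives
#' @param interval voltage bracket (mV) for the root search
#' @return named numeric vector `c(V, h, n, z)`
#' @export
resting_state <- function(params = neuron_params(), gKs = 1.5, I_ext = 0,
                          interval = c(-90, -40)) {
  f <- function(V) {
    g <- steady_state_gates(V)
    hh_derivatives(c(V = V, h = g$h_inf, n = g$n_inf, z = g$z_inf),
                   params, gKs, I_ext)[["dV"]]
  }
  V <- stats::uniroot(f, interval, tol = 1e-10)$root
  g <- steady_state_gates(V)
  c(V = V, h = g$h_inf, n = g$n_inf, z = g$z_inf)
}

#' Simulate a single isolated neuron
#'
#' Integrates one cell with the package's fixed-step RK4 integrator
#' (default dt = 0.05 ms) under a constant current step.
#'
#' @inheritParams hh_derivatives
#' @param I constant applied current (uA/cm^2)
#' @param duration simulated time (ms)
#' @param dt integration step (ms)
#' @param v0 initial membrane potential (mV); gates start at steady state
#' @param record_voltage record the voltage trace (sampled every `record_every` ms)
#' @param record_every voltage sampling interval (ms)
#' @return list with `spike_times` (ms; upward 0 mV crossings, 2 ms lockout)
#'   and, if requested, `times` and `V`
#' @export
simulate_cell <- function(params = neuron_params(), gKs = 0, I = 0,
                          duration = 2000, dt = 0.05, v0 = -65,
                          record_voltage = FALSE, record_every = 0.05) {
  if (!is.finite(gKs) || gKs < 0 || gKs > 1.5)
    stop("gKs must lie in [0, 1.5] mS/cm^2")
  res <- .sim_network_cpp(
    n_cells = 1L, is_exc = 1L, gks = gKs,
    edge_ptr = c(0L, 0L), edge_tgt = integer(0), edge_w = numeric(0),
    idrive = I, noise_on = FALSE, noise_rate = 0, noise_amp = 0,
    noise_width = 0, tau_e = 3, tau_i = 3, e_exc = 0, e_inh = -75,
    params = .params_vec(params), dt = dt, duration = duration,
    lockout_ms = 2, v0 = v0,
    record_ids = if (record_voltage) 0L else integer(0),
    record_every = if (record_voltage) record_every else 0,
    record_syn = FALSE)
  out <- list(spike_times = res$spike_time)
  if (record_voltage) {
    out$times <- res$rec_times
    out$V <- drop(res$voltages)
  }
  out
}

#' Frequency-current (f-I) relation
#'
#' Steady firing frequency after adaptation has converged, for a set of
#' constant current steps. The initial transient is discarded before
#' counting spikes (tau_z = 75 ms implies adaptation settles within about
#' five time constants, hence the 500 ms default).
#'
#' @inheritParams simulate_cell
#' @param I_values currents to probe (uA/cm^2)
#' @param transient discarded initial span (ms)
#' @return data.frame with columns `I` and `freq` (Hz)
#' @export
f_I_curve <- function(params = neuron_params(), gKs = 0,
                      I_values = seq(0, 4, by = 0.5),
                      duration = 3000, transient = 500, dt = 0.05) {
  stopifnot(duration > transient)
  freq <- vapply(I_values, function(I) {
    st <- simulate_cell(params, gKs, I, duration = duration, dt = dt)$spike_times
    st <- st[st > transient]
    1000 * length(st) / (duration - transient)
  }, numeric(1))
  data.frame(I = I_values, freq = freq)
}

#' Spike-frequency-adaptation profile
#'
#' Ordered inter-spike intervals under a constant current step, the
#' signature of M-current mediated adaptation: for large `gKs` the ISI
#' sequence lengthens towards a plateau, for `gKs = 0` it is flat.
#'
#' @inheritParams simulate_cell
#' @param I_step applied current (uA/cm^2), should exceed rheobase
#' @return numeric vector of inter-spike intervals (ms)
#' @export
sfa_profile <- function(params = neuron_params(), gKs = 1.5, I_step = 1.5,
                        duration = 2000, dt = 0.05) {
  st <- simulate_cell(params, gKs, I_step, duration = duration, dt = dt)$spike_times
  if (length(st) < 3)
    stop("fewer than 3 spikes: insufficient data for an ISI profile")
  diff(st)
}
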