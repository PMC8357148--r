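test_that("steady-state gates hit their half-(in)activation voltages and are monotone", {
  expect_equal(steady_state_gates(-30)$m_inf, 0.5)
  expect_equal(steady_state_gates(-40.5)$h_inf, 0.5)
  expect_equal(steady_state_gates(-30)$n_inf, 0.5)
  expect_equal(steady_state_gates(-39)$z_inf, 0.5)

  V <- seq(-120, 40, by = 0.5)
  g <- steady_state_gates(V)
  for (nm in c("m_inf", "h_inf", "n_inf", "z_inf")) {
    expect_true(all(g[[nm]] > 0 & g[[nm]] < 1))
  }
  expect_true(all(diff(g$m_inf) > 0))
  expect_true(all(diff(g$n_inf) > 0))
  expect_true(all(diff(g$z_inf) > 0))
  expect_true(all(diff(g$h_inf) < 0))
  expect_error(steady_state_gates(NaN), "finite")
})

test_that("gate time constants match their sigmoid midpoints, bounds and limits", {
  tc <- gate_time_constants(-40.5)
  expect_equal(tc$tau_h, 0.37 + 2.78 * 0.5)
  expect_equal(gate_time_constants(-27)$tau_n, 0.37 + 1.85 * 0.5)

  V <- seq(-120, 60, by = 0.5)
  tc <- gate_time_constants(V)
  expect_true(all(tc$tau_h > 0.37 & tc$tau_h < 0.37 + 2.78))
  expect_true(all(tc$tau_n > 0.37 & tc$tau_n < 0.37 + 1.85))
  expect_true(all(diff(tc$tau_h) < 0))
  expect_true(all(diff(tc$tau_n) < 0))
  far <- gate_time_constants(300)
  expect_equal(far$tau_h, 0.37, tolerance = 1e-6)
  expect_equal(far$tau_n, 0.37, tolerance = 1e-6)
  expect_error(gate_time_constants(Inf), "finite")
})

test_that("the resting state found by root-solving is a fixed point of the dynamics", {
  rs <- resting_state(gKs = 1.5, I_ext = 0)
  d <- hh_derivatives(rs, gKs = 1.5, I_ext = 0)
  expect_true(all(abs(d) < 1e-8))
})

test_that("the M-current term vanishes at zero conductance and at the K+ reversal", {
  st <- c(V = -60, h = 0.5, n = 0.3, z = 0.7)
  # gKs = 0: dV/dt independent of z
  d1 <- hh_derivatives(st, gKs = 0)
  st2 <- st; st2["z"] <- 0.1
  d2 <- hh_derivatives(st2, gKs = 0)
  expect_equal(d1[["dV"]], d2[["dV"]])
  # V = VK: IKs = 0, so dV/dt is the same for any gKs
  stK <- c(V = -90, h = 0.5, n = 0.3, z = 0.7)
  expect_equal(hh_derivatives(stK, gKs = 0)[["dV"]],
               hh_derivatives(stK, gKs = 1.5)[["dV"]])
  expect_error(hh_derivatives(st, gKs = 2), "gKs")
  expect_error(hh_derivatives(st, gKs = -0.1), "gKs")
})

test_that("gates stay in [0,1] when integrating from random valid states", {
  set.seed(42)
  p <- neuron_params()
  for (rep in 1:8) {
    y <- c(V = runif(1, -90, 0), h = runif(1), n = runif(1), z = runif(1))
    dt <- 0.05
    for (step in 1:2000) {  # 100 ms
      k1 <- hh_derivatives(y, p, gKs = 1.0, I_ext = 1)
      k2 <- hh_derivatives(y + dt / 2 * k1, p, gKs = 1.0, I_ext = 1)
      k3 <- hh_derivatives(y + dt / 2 * k2, p, gKs = 1.0, I_ext = 1)
      k4 <- hh_derivatives(y + dt * k3, p, gKs = 1.0, I_ext = 1)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      names(y) <- c("V", "h", "n", "z")
    }
    expect_true(all(y[2:4] >= -1e-6 & y[2:4] <= 1 + 1e-6))
    expect_true(abs(y[["V"]]) < 120)
  }
})

test_that("f-I curve matches the fine-accuracy ODE oracle and orders with gKs", {
  # 81.2 Hz at gKs = 0, I = 1.5 uA/cm^2, computed with deSolve::ode (lsoda,
  # rtol = atol = 1e-10) over 3 s with a 500 ms transient discard
  f <- f_I_curve(gKs = 0, I_values = 1.5)$freq
  expect_equal(f, 81.2, tolerance = 0.02)

  I <- c(1.0, 1.5, 2.0, 3.0)
  f0 <- f_I_curve(gKs = 0, I_values = I)$freq
  f6 <- f_I_curve(gKs = 0.6, I_values = I)$freq
  f15 <- f_I_curve(gKs = 1.5, I_values = I)$freq
  expect_true(all(f0 >= f6))
  expect_true(all(f6 >= f15))
  expect_true(all(f15 > 0))
  # below rheobase at full adaptation conductance
  expect_equal(f_I_curve(gKs = 1.5, I_values = 0.1)$freq, 0)
})

test_that("spike-frequency adaptation appears with gKs and not without", {
  isi0 <- sfa_profile(gKs = 0, I_step = 1.5)
  expect_true(max(abs(isi0[-1] - isi0[2])) / isi0[2] < 0.01)

  isi15 <- sfa_profile(gKs = 1.5, I_step = 1.5)
  expect_true(all(diff(isi15) > -1e-9))          # non-decreasing
  expect_gt(utils::tail(isi15, 1) / isi15[1], 1.5)

  # intermediate conductance adapts intermediately (checked against the
  # deSolve oracle during development: ratio 2.02 at gKs = 0.6)
  r06 <- utils::tail(sfa_profile(gKs = 0.6, I_step = 1.5), 1) /
    sfa_profile(gKs = 0.6, I_step = 1.5)[1]
  r0 <- utils::tail(isi0, 1) / isi0[1]
  r15 <- utils::tail(isi15, 1) / isi15[1]
  expect_true(r0 < r06 && r06 < r15)
  expect_equal(r06, 2.02, tolerance = 0.02)

  expect_error(sfa_profile(gKs = 1.5, I_step = -1, duration = 300),
               "insufficient")
})

test_that("halving the step leaves single-cell spike times nearly unchanged", {
  st1 <- simulate_cell(gKs = 0.6, I = 1.5, duration = 1000, dt = 0.05)$spike_times
  st2 <- simulate_cell(gKs = 0.6, I = 1.5, duration = 1000, dt = 0.025)$spike_times
  expect_equal(length(st1), length(st2))
  expect_lt(max(abs(st1 - st2)), 1)  # < 1 ms over a 1 s run
})

test_that("the resting state is stable to small perturbations at gKs = 1.5", {
  rs <- resting_state(gKs = 1.5)
  for (dv in c(-1, 0.5, 1)) {
    tr <- simulate_cell(gKs = 1.5, I = 0, duration = 50, v0 = rs[["V"]] + dv,
                        record_voltage = TRUE)
    expect_lt(abs(utils::tail(tr$V, 1) - rs[["V"]]), abs(dv))
  }
})
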