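# minimal hand-built network: cells 1,2 excitatory, cell 3 inhibitory;
# 1 -> 2 and 3 -> 2 synapses only
micro_topology <- function(wEE = 0.01, wIE = 0.04) {
  syn <- synapse_params()
  structure(list(
    geom = NULL, syn = syn,
    kind = c("E", "E", "I"),
    positions = cbind(c(0, 1, 2), c(0, 0, 0)),
    edges = data.frame(src = c(1L, 3L), tgt = c(2L, 2L), w = c(wEE, wIE))),
    class = "network_topology")
}

test_that("identical configuration and seed give bit-identical rasters", {
  topo <- default_topo()
  map <- uniform_gks_map(0.2)
  cfg <- sim_config(duration = 1200, transient = 200)
  r1 <- run_simulation(topo, map, noise = noise_config(enabled = TRUE),
                       cfg = cfg, seed = 5)
  r2 <- run_simulation(topo, map, noise = noise_config(enabled = TRUE),
                       cfg = cfg, seed = 5)
  expect_identical(r1$events, r2$events)
  r3 <- run_simulation(topo, map, noise = noise_config(enabled = TRUE),
                       cfg = cfg, seed = 6)
  expect_false(identical(r1$events, r3$events))
})

test_that("raster invariants hold: ID ranges, time bounds, refractory gaps", {
  topo <- default_topo()
  r <- run_simulation(topo, uniform_gks_map(0.2),
                      cfg = sim_config(duration = 1200, transient = 200),
                      seed = 1)
  ev <- r$events
  expect_true(all(ev$id >= 1 & ev$id <= 500))
  expect_true(all(ev$time > 0 & ev$time <= 1200))
  isi_ok <- tapply(ev$time, ev$id, function(tt) all(diff(sort(tt)) >= 2))
  expect_true(all(unlist(isi_ok)))
})

test_that("with no drive and no noise the network rests and the raster is empty", {
  topo <- default_topo()
  r <- run_simulation(topo, uniform_gks_map(1.5), drive = drive_config(0),
                      cfg = sim_config(duration = 500, transient = 100),
                      seed = 1)
  expect_equal(nrow(r$events), 0)
})

test_that("the conductance accumulators reproduce the per-spike kernel sum", {
  topo <- micro_topology()
  # drive cells 1 and 3 above threshold; record the target's conductances
  cfg <- sim_config(duration = 500, transient = 0, record_ids = 2,
                    record_every = 1, record_syn = TRUE)
  r <- run_simulation(topo, c(0.2, 1.5, 0.2),
                      drive = drive_config(3, I_base_I = 3),
                      cfg = cfg, seed = 2)
  ev <- r$events
  t1 <- ev$time[ev$id == 1]
  t3 <- ev$time[ev$id == 3]
  expect_gt(length(t1), 5)
  tau <- 3
  for (k in c(100, 250, 499)) {
    t <- r$rec_times[k]
    ge_direct <- 0.01 * sum(exp(-(t - t1[t1 <= t]) / tau))
    gi_direct <- 0.04 * sum(exp(-(t - t3[t3 <= t]) / tau))
    expect_equal(r$ge[k, 1], ge_direct, tolerance = 1e-10)
    expect_equal(r$gi[k, 1], gi_direct, tolerance = 1e-10)
  }
})

test_that("synaptic driving forces follow the printed form", {
  # at the inhibitory reversal the inhibitory current is zero, and one
  # excitatory spike of weight w contributes w * (V - 0) at zero lag and
  # w * e^-1 * (V - 0) one time constant later
  syn <- synapse_params()
  gi <- 0.5
  expect_equal(gi * (-75 - syn$E_inh), 0)
  w <- 0.01
  expect_equal(w * (-60 - syn$E_exc), -0.6)
  expect_equal(w * exp(-3 / syn$tau_exc), w * exp(-1))
})

test_that("halving the integration step changes the population rate by < 3%", {
  topo <- default_topo()
  map <- generate_gks_map(cbind(10L, 10L), 4.2)
  rate <- function(dt) {
    r <- run_simulation(topo, map,
                        cfg = sim_config(dt = dt, duration = 2000,
                                         transient = 500), seed = 3)
    sum(r$events$time > 500) / 1.5
  }
  r1 <- rate(0.05); r2 <- rate(0.025)
  expect_lt(abs(r1 - r2) / r2, 0.03)
})

test_that("numerical blow-up is detected and reported", {
  topo <- micro_topology()
  expect_error(
    run_simulation(topo, c(0.2, 0.2, 0.2), drive = drive_config(1e5),
                   cfg = sim_config(duration = 50, transient = 0), seed = 1),
    "blow-up")
})

test_that("a stimulus equal to the background drive is a no-op", {
  topo <- default_topo()
  map <- uniform_gks_map(0.5)
  cfg <- sim_config(duration = 800, transient = 200)
  r0 <- run_simulation(topo, map, drive = drive_config(3.0), cfg = cfg, seed = 4)
  r1 <- run_simulation(topo, map,
                       drive = drive_config(3.0, target_ids = 1:12,
                                            I_target = 3.0),
                       cfg = cfg, seed = 4)
  expect_identical(r0$events, r1$events)
})

test_that("raster round-trips through the delimited text format", {
  topo <- default_topo()
  r <- run_simulation(topo, uniform_gks_map(0.2),
                      cfg = sim_config(duration = 700, transient = 200), seed = 1)
  tf <- tempfile(fileext = ".tsv")
  write_raster(r, tf)
  r2 <- read_raster(tf)
  expect_equal(r2$events$time, r$events$time)
  expect_equal(r2$events$id, r$events$id)
  expect_equal(r2$duration, r$duration)
  unlink(tf)
})
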