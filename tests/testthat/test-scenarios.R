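# Scenario registry, sweep machinery, and the robust ordinal behavior of
# the network under the standard manipulations.

test_that("scenario registry is well-formed and rejects unknown names", {
  reg <- scenario_registry()
  expect_true(all(c("control", "sto_removed", "sto_fast", "gaba3",
                    "gc_off", "wmcgc8", "ngc_225") %in% names(reg)))
  expect_false(any(duplicated(names(reg))))
  keys <- names(obgamma:::sim_defaults())
  for (sc in reg) expect_true(all(names(sc$overrides) %in% keys))
  expect_error(run_scenario("not_a_scenario"), "registered")
  expect_error(run_scenario("control", seeds = integer(0)), "non-empty")
})

test_that("sweep validates inputs and returns an empty table for no values", {
  expect_error(sweep_parameter("no_such_key", 1), "unknown")
  expect_error(sweep_parameter("w_gc_mc", "a"), "numeric")
  empty <- sweep_parameter("w_gc_mc", numeric(0))
  expect_equal(nrow(empty), 0)
})

test_that("granule inhibition is required for MC spike synchronization", {
  # removing GC->MC inhibition lowers the synchronization index and
  # disinhibits MCs
  expect_gt(batch_mean("control", "si"), batch_mean("gc_off", "si"))
  expect_gt(batch_mean("gc_off", "mc_rate_hz"),
            batch_mean("control", "mc_rate_hz"))
})

test_that("removing mitral STOs weakens oscillation power", {
  ctrl <- get_batch("control")
  nosto <- get_batch("sto_removed")
  expect_gt(oscillation_index(ctrl$per_seed$peak_power,
                              ctrl$per_seed$peak_power),
            oscillation_index(nosto$per_seed$peak_power,
                              ctrl$per_seed$peak_power))
})

test_that("faster GABA_A decay speeds the rhythm; slower decay suppresses firing", {
  f18 <- batch_mean("control", "peak_freq_hz")
  expect_gt(batch_mean("gaba3", "peak_freq_hz"), f18)
  # total integrated inhibition grows with the decay constant, so MC and
  # GC rates decline monotonically from 3 ms to 30 ms
  expect_gt(batch_mean("gaba3", "mc_rate_hz"), batch_mean("control", "mc_rate_hz"))
  expect_gt(batch_mean("control", "mc_rate_hz"), batch_mean("gaba30", "mc_rate_hz"))
  expect_gt(batch_mean("gaba3", "gc_rate_hz"), batch_mean("gaba30", "gc_rate_hz"))
})

test_that("fast intrinsic STOs disrupt gamma; fast inhibition restores it", {
  ctrl <- get_batch("control")
  fast18 <- get_batch("sto_fast")
  fast3 <- get_batch("sto_fast_gaba3")
  oi_fast18 <- oscillation_index(fast18$per_seed$peak_power,
                                 ctrl$per_seed$peak_power)
  oi_fast3 <- oscillation_index(fast3$per_seed$peak_power,
                                ctrl$per_seed$peak_power)
  expect_gt(oi_fast3, oi_fast18)
  expect_gt(mean(fast3$per_seed$dominant), 0.5)
  expect_gt(scenario_mean(fast3, "si"), scenario_mean(fast18, "si"))
})

test_that("strong excitatory weights shift activity from MCs to GCs", {
  ctrl <- get_batch("control")
  w8 <- get_batch("wmcgc8")
  expect_gt(scenario_mean(w8, "gc_rate_hz"), scenario_mean(ctrl, "gc_rate_hz"))
  expect_lt(scenario_mean(w8, "mc_rate_hz"), scenario_mean(ctrl, "mc_rate_hz"))
  expect_gt(mean(w8$per_seed$dominant), 0.5)
})

test_that("PGC spikes are uniform over the gamma cycle; MC and GC are not", {
  cfg <- get_batch("control")$cfg
  rec <- run_simulation(cfg, seed = 1)
  win <- analysis_window(cfg)
  lf <- compute_slfp(rec, window_ms = win)
  peaks <- slfp_peak_times(lf)$peak_t_ms
  pooled <- function(pop) {
    sp <- unlist(rec$spikes[[pop]], use.names = FALSE)
    spike_phases(sp[sp >= win[1] & sp < win[2]], peaks)$phase
  }
  # Rayleigh-style criterion: n * kappa^2 compares against uniformity
  rayleigh_z <- function(phi) length(phi) * synchronization_index(phi)^2
  expect_gt(rayleigh_z(pooled("mc")), 3)
  expect_gt(rayleigh_z(pooled("gc")), 3)
  expect_lt(rayleigh_z(pooled("pgc")), 3)
})

test_that("granule population scaling preserves the gamma operating point", {
  ctrl <- get_batch("control")
  n225 <- get_batch("ngc_225")
  expect_gt(mean(n225$per_seed$dominant), 0.5)
  expect_lt(abs(scenario_mean(n225, "peak_freq_hz") -
                scenario_mean(ctrl, "peak_freq_hz")) /
            scenario_mean(ctrl, "peak_freq_hz"), 0.25)
  expect_lt(abs(scenario_mean(n225, "mc_rate_hz") -
                scenario_mean(ctrl, "mc_rate_hz")) /
            scenario_mean(ctrl, "mc_rate_hz"), 0.25)
})
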