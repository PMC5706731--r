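# First-order synaptic kinetics, presynaptic sigmoid, Mg2+ block.

test_that("presynaptic activation sigmoid matches closed-form values", {
  gaba <- synapse_spec("GABA_A")
  ampa <- synapse_spec("AMPA")
  # half-activation at theta by symmetry
  expect_equal(presynaptic_activation(-40, gaba), 0.5)
  expect_equal(presynaptic_activation(0, ampa), 0.5)
  # GABA_A at -30 mV: 1 / (1 + e^-5)
  expect_equal(presynaptic_activation(-30, gaba), 1 / (1 + exp(-5)),
               tolerance = 1e-12)
  # spike-gated excitation is negligible at subthreshold potentials
  expect_lt(presynaptic_activation(-60, ampa), 1e-10)
  # strictly increasing
  v <- seq(-80, 20, by = 0.5)
  expect_true(all(diff(presynaptic_activation(v, gaba)) > 0))
})

test_that("graded vs spike-gated regimes at subthreshold voltage", {
  # a presynaptic cell held at -45 mV transmits through GABA_A but not
  # through AMPA/NMDA
  expect_gte(presynaptic_activation(-45, synapse_spec("GABA_A")), 0.07)
  expect_lt(presynaptic_activation(-45, synapse_spec("AMPA")), 1e-10)
  expect_lt(presynaptic_activation(-45, synapse_spec("NMDA")), 1e-10)
})

test_that("Mg block matches the printed formula and its limits", {
  nmda <- synapse_spec("NMDA", mg_mm = 1)
  expect_equal(mg_block(0, nmda), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  # no block without Mg
  free <- synapse_spec("NMDA", mg_mm = 0)
  expect_equal(mg_block(c(-80, -40, 0, 40), free), rep(1, 4))
  # AMPA / GABA_A are unblocked
  expect_equal(mg_block(-70, synapse_spec("AMPA")), 1)
  expect_equal(mg_block(-70, synapse_spec("GABA_A")), 1)
  # monotone increasing in V
  v <- seq(-90, 30, by = 1)
  expect_true(all(diff(mg_block(v, nmda)) > 0))
  # NMDA current at -70 mV is well below its -20 mV value for equal s
  i70 <- abs(synaptic_current(0.5, -70, nmda))
  i20 <- abs(synaptic_current(0.5, -20, nmda))
  expect_lt(i70 / i20 / (70 / 20), 0.3)
})

test_that("gating fixed point and free decay match closed forms", {
  ampa <- synapse_spec("AMPA")
  # F = 1 held: s -> alpha/(alpha+beta) = 1/(1 + 1/5.5)
  s <- 0
  for (k in 1:4000) s <- step_gating(s, v_pre_mv = 60, dt_ms = 0.5, spec = ampa)
  expect_equal(s, 1 / (1 + 1 / 5.5), tolerance = 1e-6)
  # F = 0 held: exponential decay with tau_decay
  s0 <- 0.8
  s <- step_gating(s0, v_pre_mv = -80, dt_ms = 11, spec = ampa)
  expect_equal(s, s0 * exp(-11 / 5.5), tolerance = 1e-9)
})

test_that("exponential gating update matches high-resolution integration", {
  # oracle: explicit Euler at 1000x finer resolution over a random
  # piecewise-constant presynaptic voltage path
  set.seed(11)
  for (spec in list(synapse_spec("AMPA"), synapse_spec("NMDA"),
                    synapse_spec("GABA_A"))) {
    alpha <- 1 / spec$tau_rise_ms
    beta <- 1 / spec$tau_decay_ms
    dt <- 0.05
    v_path <- stats::runif(400, -80, 20)
    s_exact <- 0
    s_oracle <- 0
    for (v in v_path) {
      s_exact <- step_gating(s_exact, v, dt, spec)
      f <- presynaptic_activation(v, spec)
      ds <- function(s) alpha * f * (1 - s) - beta * s
      h <- dt / 20
      for (j in 1:20) {
        k1 <- ds(s_oracle)
        k2 <- ds(s_oracle + h / 2 * k1)
        k3 <- ds(s_oracle + h / 2 * k2)
        k4 <- ds(s_oracle + h * k3)
        s_oracle <- s_oracle + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    }
    expect_equal(s_exact, s_oracle, tolerance = 1e-6)
    expect_true(s_exact >= 0 && s_exact <= 1)
  }
})

test_that("gating stays in [0,1] under arbitrary presynaptic paths", {
  set.seed(21)
  spec <- synapse_spec("GABA_A")
  for (rep in 1:20) {
    s <- stats::runif(1)
    dt <- stats::runif(1, 0.001, 5)
    for (v in stats::runif(200, -120, 60)) {
      s <- step_gating(s, v, dt, spec)
      expect_true(s >= 0 && s <= 1)
    }
  }
})

test_that("NMDA gating accumulates over spike trains", {
  nmda <- synapse_spec("NMDA")
  run_train <- function(spike_starts, total_ms) {
    s <- 0
    smax <- 0
    dt <- 0.05
    for (t in seq(0, total_ms, by = dt)) {
      in_spike <- any(t >= spike_starts & t < spike_starts + 1)
      s <- step_gating(s, if (in_spike) 20 else -70, dt, nmda)
      smax <- max(smax, s)
    }
    smax
  }
  one <- run_train(5, 60)
  ten <- run_train(5 + 25 * (0:9), 300)
  expect_lt(one, 0.05)           # single 1 ms spike: small increment
  expect_gt(ten, 5 * one)        # accumulation across the train
  expect_lte(ten, 1)             # saturation bound
})

test_that("synaptic current reverses at E_syn and scales with W*g", {
  gaba <- synapse_spec("GABA_A", w = 2)
  expect_equal(synaptic_current(1, -80, gaba), 0)
  # W = 2, g = 2 nS, s = 1, V = -40: 4 nS * 40 mV = +0.16 nA outward
  expect_equal(synaptic_current(1, -40, gaba), 0.16, tolerance = 1e-12)
  # final maximal conductance equals W * g_syn
  i1 <- synaptic_current(1, -60, synapse_spec("GABA_A", w = 1))
  i3 <- synaptic_current(1, -60, synapse_spec("GABA_A", w = 3))
  expect_equal(i3, 3 * i1)
})

test_that("invalid synapse parameters are rejected", {
  expect_error(synapse_spec("AMPA", w = -1), "w")
  expect_error(synapse_spec("AMPA", tau_rise_ms = 0), "tau_rise_ms")
  expect_error(step_gating(0.5, -60, dt_ms = 0, synapse_spec("AMPA")),
               "dt")
  expect_error(step_gating(1.5, -60, dt_ms = 1, synapse_spec("AMPA")),
               "\\[0, 1\\]")
})
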