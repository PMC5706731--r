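# Isolated-cell anchors of the mitral cell model: subthreshold
# oscillations, mixed-mode firing, kinetics variants, dendritic
# propagation.

mc_cell <- build_mitral_cell()

sto_freq <- function(cell, i_na, dur = 2500, skip = 500) {
  r <- simulate_cell(cell, i_na, duration_ms = dur, dt_ms = 0.02)
  v <- r$v[r$t_ms > skip, 1]
  list(sto = subthreshold_spectrum(v, 1000 / 0.5),
       rate = sum(r$spikes > skip) / (dur - skip) * 1000)
}

test_that("resting mitral cell is quiescent without input", {
  r <- simulate_cell(mc_cell, 0, duration_ms = 2000, dt_ms = 0.02)
  expect_equal(length(r$spikes), 0)
  v_late <- r$v[r$t_ms > 1500, 1]
  expect_lt(diff(range(v_late)), 1)     # stable resting potential
})

test_that("0.2 nA injection produces mixed-mode dynamics with ~29 Hz STOs", {
  res <- sto_freq(mc_cell, 0.2)
  expect_true(res$sto$dominant)
  expect_equal(res$sto$freq_hz, 29, tolerance = 0.1)
  # spikes present but sparser than the STO cycle
  expect_gt(res$rate, 2)
  expect_lt(res$rate, res$sto$freq_hz)
})

test_that("STO frequency grows with depolarization", {
  f <- vapply(c(0.15, 0.2, 0.25), function(i) {
    sto_freq(mc_cell, i, dur = 2000)$sto$freq_hz
  }, numeric(1))
  expect_true(all(diff(f) >= -0.5))
  expect_gt(f[3], f[1])
})

test_that("somatic spikes reach the distal dendrite fast and full-sized", {
  r <- simulate_cell(mc_cell, 2, duration_ms = 50, dt_ms = 0.002,
                     inj_start_ms = 10, inj_stop_ms = 14,
                     record = c("soma", "dend7"), sample_ms = 0.01)
  cross <- function(v) {
    r$t_ms[which(v[-1] >= 0 & v[-length(v)] < 0)[1] + 1]
  }
  delay <- cross(r$v[, "dend7"]) - cross(r$v[, "soma"])
  expect_lt(delay, 1)
  # near-full amplitude: spike height at the distal site >= 80% of somatic
  base <- -60
  expect_gt(max(r$v[, "dend7"]) - base, 0.8 * (max(r$v[, "soma"]) - base))
})

test_that("cation substitution removes the STO peak but preserves f-I", {
  cat_cell <- substitute_nap_with_cat(mc_cell)
  expect_error(substitute_nap_with_cat(cat_cell), "already")
  # direct evaluation of the ohmic current: g_CAT (v - E_CAT)
  # at v = -60 mV, 0.26 mS/cm2: -15.6 uA/cm2 (inward)
  expect_equal(0.26 * (-60 - 0), -15.6)
  expect_equal(0.26 * (0 - 0), 0)
  # densities swapped in every compartment that carried I_NaP
  had <- mc_cell$comps$g_nap_us > 0
  expect_true(all(cat_cell$comps$g_nap_us[had] == 0))
  expect_equal(cat_cell$comps$g_cat_us[had],
               0.26 * mc_cell$comps$area_cm2[had] * 1000)
  # subthreshold spectrum loses its distinct peak
  ctrl <- sto_freq(mc_cell, 0.2)
  sub <- sto_freq(cat_cell, 0.2)
  expect_lt(sub$sto$power / ctrl$sto$power, 0.5)
  # f-I curves agree within 15% over 0.1-0.3 nA (2 s counting windows)
  for (i in c(0.1, 0.2, 0.3)) {
    rc <- sto_freq(mc_cell, i)$rate
    rs <- sto_freq(cat_cell, i)$rate
    expect_lt(abs(rs - rc) / max(rc, 2), 0.15)
  }
})

test_that("fast STO kinetics shift the peak to ~44 Hz and round-trip", {
  fast <- set_fast_sto_kinetics(mc_cell)
  expect_error(set_fast_sto_kinetics(fast), "default")
  expect_equal(fast$chan$tau_ks_ms, mc_cell$chan$tau_ks_ms / 2)
  expect_equal(fast$comps$g_ks_us, mc_cell$comps$g_ks_us * 1.6)
  expect_equal(fast$comps$g_nap_us, mc_cell$comps$g_nap_us * 1.3)
  res_f <- sto_freq(fast, 0.2)
  expect_true(res_f$sto$dominant)
  expect_equal(res_f$sto$freq_hz, 44, tolerance = 0.1)
  # firing rate approximately preserved
  res_c <- sto_freq(mc_cell, 0.2)
  expect_lt(abs(res_f$rate - res_c$rate) / max(res_c$rate, 2), 0.15)
  # reverting restores the default spectral peak
  back <- set_default_sto_kinetics(fast)
  expect_equal(sto_freq(back, 0.2)$sto$freq_hz, res_c$sto$freq_hz,
               tolerance = 1e-8)
})

test_that("granule and periglomerular cells build with valid structure", {
  gc <- build_granule_cell(n_spines = 5)
  expect_equal(nrow(gc$comps), 6)
  expect_equal(gc$comps$parent[-1], rep(1L, 5))
  pgc <- build_periglomerular_cell()
  expect_equal(nrow(pgc$comps), 2)
  expect_true(pgc$osn_gain > 0)
})

test_that("invalid cell parameters are rejected with the field named", {
  p <- default_cell_params()
  p$mc$soma$g_na <- -5
  expect_error(build_mitral_cell(p), "g_na")
  p2 <- default_cell_params()
  p2$mc$ks$tau_ms <- 0
  expect_error(build_mitral_cell(p2), "tau_ms")
  p3 <- default_cell_params()
  p3$mc$soma$l_um <- NULL
  expect_error(build_mitral_cell(p3), "l_um")
})
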