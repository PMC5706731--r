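# sLFP filtering, spectra, spike phases, synchronization and oscillation
# indices, rates and histograms.

make_tone <- function(freq_hz, fs_hz = 2000, dur_s = 3, amp = 1, phase = 0) {
  t <- seq(0, dur_s, by = 1 / fs_hz)
  list(t_ms = t * 1000, x = amp * cos(2 * pi * freq_hz * t + phase))
}

test_that("zero-phase band-pass keeps the passband and rejects DC/stopband", {
  fs <- 2000
  tone <- make_tone(50, fs)
  y <- bandpass_zerophase(tone$x, fs)
  mid <- seq(1000, length(y) - 1000)
  # amplitude within 2%
  expect_equal(max(y[mid]), 1, tolerance = 0.02)
  # zero phase: peak positions coincide with the input's (< 1 degree)
  py <- trace_peaks(y[mid], tone$t_ms[mid])
  px <- trace_peaks(tone$x[mid], tone$t_ms[mid])
  shift_ms <- stats::median(vapply(py, function(p) min(abs(px - p)), numeric(1)))
  expect_lt(shift_ms, (1 / 360) * 20)  # 1 degree of a 20 ms cycle
  # DC rejected
  expect_lt(max(abs(bandpass_zerophase(rep(3, 6000), fs)[mid])), 0.01)
  # 5 Hz stopband attenuated below 10%
  slow <- make_tone(5, fs)
  expect_lt(max(abs(bandpass_zerophase(slow$x, fs)[mid])), 0.1)
  expect_error(bandpass_zerophase(rnorm(30), fs), "short")
})

test_that("peak frequency recovers known tones and flags flat spectra", {
  fs <- 2000
  set.seed(14)
  tone <- make_tone(32.4, fs)
  x <- tone$x + rnorm(length(tone$x), sd = sqrt(0.5 / 10)) # SNR ~ 10
  pk <- peak_frequency(power_spectrum(x, fs))
  expect_true(pk$dominant)
  expect_equal(pk$freq_hz, 32.4, tolerance = 0.6 / 32.4)
  # white noise alone: no dominant peak
  pn <- peak_frequency(power_spectrum(rnorm(6000), fs))
  expect_false(pn$dominant)
  expect_true(is.na(pn$freq_hz))
  # dominant of two tones
  two <- make_tone(30, fs)$x + 0.5 * make_tone(60, fs)$x
  expect_equal(peak_frequency(power_spectrum(two, fs))$freq_hz, 30,
               tolerance = 0.02)
})

test_that("spike phases follow the peak-referenced linear convention", {
  peaks <- seq(0, 1000, by = 25)          # 40 Hz reference
  # spike exactly at a peak -> phase 0
  expect_equal(spike_phases(c(100), peaks)$phase, 0)
  # spike at the midpoint -> phase pi
  expect_equal(spike_phases(c(112.5), peaks)$phase, pi)
  # quarter cycle -> pi/2
  expect_equal(spike_phases(c(106.25), peaks)$phase, pi / 2)
  # spikes outside the bracketed range are excluded and counted
  ph <- spike_phases(c(-5, 500, 1400), peaks)
  expect_equal(length(ph$phase), 1)
  expect_equal(ph$n_excluded, 2)
})

test_that("synchronization index identities and uniform-phase scaling", {
  expect_equal(synchronization_index(rep(1.3, 50)), 1)
  expect_equal(synchronization_index(c(0, pi / 2, pi, 3 * pi / 2)), 0,
               tolerance = 1e-12)
  expect_true(is.na(synchronization_index(numeric(0))))
  # invariance under global rotation
  set.seed(9)
  phi <- stats::runif(200, 0, 2 * pi)
  expect_equal(synchronization_index(phi),
               synchronization_index((phi + 1.1) %% (2 * pi)),
               tolerance = 1e-12)
  # 1e4 uniform phases: kappa ~ 1/sqrt(N) (Monte-Carlo oracle)
  k <- vapply(1:50, function(i) {
    synchronization_index(stats::runif(1e4, 0, 2 * pi))
  }, numeric(1))
  expect_equal(mean(k), 0.009, tolerance = 0.6)
  expect_true(all(k >= 0 & k <= 1))
})

test_that("trough-locked surrogate spikes give mean phase pi and kappa ~ 1", {
  fs <- 2000
  tone <- make_tone(40, fs)
  peaks <- trace_peaks(tone$x, tone$t_ms)
  troughs <- peaks[-length(peaks)] + 12.5
  ph <- spike_phases(troughs, peaks)
  expect_equal(synchronization_index(ph), 1, tolerance = 1e-3)
  mean_phase <- atan2(mean(sin(ph$phase)), mean(cos(ph$phase))) %% (2 * pi)
  expect_equal(mean_phase, pi, tolerance = 0.01)
})

test_that("oscillation index normalizes to the reference seed maximum", {
  ref <- c(2, 5, 3, 4)
  expect_equal(oscillation_index(ref, ref), mean(ref) / 5)
  expect_equal(oscillation_index(5, ref), 1)
  expect_equal(oscillation_index(2.5, ref), 0.5)
  # flat-spectrum runs contribute their low peak power, not zero
  expect_gt(oscillation_index(c(0.1, 0.2), ref), 0)
  expect_error(oscillation_index(1, numeric(0)), "reference")
})

test_that("rates and histograms conserve spikes and recover Poisson rates", {
  spikes <- list(seq(50, 950, by = 100))   # 10 spikes in 1 s
  r <- rates_and_histograms(spikes, c(0, 1000))
  expect_equal(r$rate_hz, 10)
  expect_equal(sum(r$hist), 10)
  expect_equal(length(r$hist), 200)        # 5 ms bins
  set.seed(33)
  tr <- poisson_background(20, 10000, n_cells = 10)
  rr <- rates_and_histograms(tr, c(0, 10000))
  expect_equal(rr$mean_rate_hz, 20, tolerance = 0.1)
  expect_equal(sum(rr$hist), sum(lengths(tr)))
  expect_error(rates_and_histograms(spikes, c(500, 500)), "window")
})

test_that("autocorrelation of a tone is periodic at the tone period", {
  fs <- 2000
  tone <- make_tone(40, fs)
  ac <- trace_autocorrelation(tone$x, fs, max_lag_ms = 100)
  # maximum away from zero lag sits at ~25 ms
  away <- ac[ac$lag_ms > 10, ]
  expect_equal(away$lag_ms[which.max(away$acf)], 25, tolerance = 0.03)
})

test_that("subthreshold spectrum ignores clipped spike energy", {
  fs <- 2000
  t <- seq(0, 3, by = 1 / fs)
  v <- -55 + 3 * cos(2 * pi * 29 * t)      # 29 Hz STO around -55 mV
  spike_at <- seq(500, 5500, by = 500)
  v[spike_at] <- 30                        # sparse spike samples
  ss <- subthreshold_spectrum(v, fs)
  expect_true(ss$dominant)
  expect_equal(ss$freq_hz, 29, tolerance = 0.02)
})
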