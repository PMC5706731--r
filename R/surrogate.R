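# Surrogate recordings with known ground truth (oscillation frequency,
# phase-locking concentration, rates), so the analysis pipeline can be
# validated independently of the biophysical simulator.

#' Surrogate recording specification
#'
#' @param freq_hz network oscillation frequency of the synthetic traces.
#' @param rate_hz mean spike rate per cell (Hz).
#' @param concentration circular concentration of the spike-phase
#'   distribution (0 = uniform phases; large = tight locking).
#' @param pref_phase preferred phase (radians; 0 = at the trace peak).
#' @param n_cells number of "mitral cells".
#' @param duration_ms trace duration.
#' @param amp_mv oscillation amplitude on each trace (mV).
#' @param noise_mv white-noise standard deviation per trace sample (mV).
#' @param sample_ms trace sampling interval (ms).
#' @param seed RNG seed.
#' @return list of class `surrogate_spec`.
#' @export
surrogate_spec <- function(freq_hz = 32.4, rate_hz = 14,
                           concentration = 4, pref_phase = 0,
                           n_cells = 25, duration_ms = 3000,
                           amp_mv = 1, noise_mv = 0.3,
                           sample_ms = 0.5, seed = 1) {
  stopifnot(rate_hz >= 0, duration_ms > 0, freq_hz > 0,
            concentration >= 0)
  out <- as.list(environment())
  class(out) <- "surrogate_spec"
  out
}

#' Sample phases from a wrapped unimodal (von Mises) distribution
#'
#' Inverse-CDF sampling on a fine grid; concentration 0 reduces to the
#' uniform distribution on [0, 2 pi).
#'
#' @param n number of draws.
#' @param concentration concentration parameter (>= 0).
#' @param mu mean phase (radians).
#' @return phases in [0, 2 pi).  Uses the current RNG state.
#' @export
sample_wrapped_phases <- function(n, concentration, mu = 0) {
  if (n == 0) return(numeric(0))
  if (concentration == 0) return(stats::runif(n, 0, 2 * pi))
  grid <- seq(0, 2 * pi, length.out = 4096)
  dens <- exp(concentration * (cos(grid - mu) - 1))
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  grid[findInterval(u, cdf) + 1] %% (2 * pi)
}

#' Generate a surrogate recording
#'
#' MC "somatic traces" are a common sinusoid (peak at t = 0 and every
#' period thereafter) plus independent white noise; spike times are drawn
#' by picking cycles uniformly and cycle phases from the wrapped unimodal
#' distribution, so the ground-truth locking strength is controlled by
#' `concentration`.
#'
#' @param spec a [surrogate_spec()].
#' @return a [recording()] (with empty GC/PGC populations).
#' @export
make_surrogate_recording <- function(spec) {
  set.seed(spec$seed)
  t_ms <- seq(0, spec$duration_ms, by = spec$sample_ms)
  period_ms <- 1000 / spec$freq_hz
  base <- spec$amp_mv * cos(2 * pi * spec$freq_hz * t_ms / 1000)
  v <- vapply(seq_len(spec$n_cells), function(i) {
    base + stats::rnorm(length(t_ms), sd = spec$noise_mv)
  }, numeric(length(t_ms)))
  n_cycles <- floor(spec$duration_ms / period_ms)
  spikes <- lapply(seq_len(spec$n_cells), function(i) {
    n_sp <- stats::rpois(1, spec$rate_hz * spec$duration_ms / 1000)
    if (n_sp == 0) return(numeric(0))
    cyc <- sample.int(n_cycles, n_sp, replace = TRUE) - 1
    phi <- sample_wrapped_phases(n_sp, spec$concentration, spec$pref_phase)
    t_sp <- (cyc + phi / (2 * pi)) * period_ms
    sort(unique(t_sp))
  })
  recording(
    spikes = list(mc = spikes, gc = list(), pgc = list()),
    v_mc = v, t_ms = t_ms, dt_ms = spec$sample_ms,
    meta = list(surrogate = TRUE, freq_hz = spec$freq_hz,
                concentration = spec$concentration,
                rate_hz = spec$rate_hz, seed = spec$seed))
}
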