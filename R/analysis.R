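# Analysis of network recordings: simulated LFP (band-passed mean MC
# somatic potential), FFT power spectra with interpolated peak frequency,
# spike phases relative to sLFP peaks, the vector-strength
# synchronization index, the seed-normalized oscillation index, and
# population rate / histogram summaries.

#' Zero-phase FIR band-pass filter
#'
#' Linear-phase FIR filter (window design) applied forward and backward,
#' so the output has no phase lag.  The default band is 10-100 Hz, the
#' band used for the simulated LFP.
#'
#' @param x signal (numeric vector).
#' @param fs_hz sampling rate (Hz).
#' @param band_hz two-element band edges (Hz).
#' @param order filter order; defaults to one third of a second of taps,
#'   ample for a 10 Hz lower edge at the 2 kHz trace sampling rate.
#' @return the filtered signal (same length).
#' @export
bandpass_zerophase <- function(x, fs_hz, band_hz = c(10, 100),
                               order = NULL) {
  if (is.null(order)) order <- round(fs_hz / 3)
  order <- min(order, floor((length(x) - 1) / 3) - 1)
  if (order < 16) stop("analysis window too short for the filter order")
  if (order %% 2 == 1) order <- order - 1
  fir <- signal::fir1(order, band_hz / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(fir, x))
}

#' Simulated local field potential
#'
#' The sLFP is the mean of all MC somatic membrane potentials, band-pass
#' filtered 10-100 Hz with a zero-phase FIR filter.
#'
#' @param rec a `recording` (see [run_simulation()]) or a numeric matrix
#'   of MC somatic traces (samples x cells).
#' @param window_ms optional two-element analysis window (ms) to crop to
#'   before filtering.
#' @param band_hz filter band (Hz).
#' @return a list with `t_ms`, `slfp` (filtered trace), `raw` (unfiltered
#'   mean potential) and `fs_hz`.
#' @export
compute_slfp <- function(rec, window_ms = NULL, band_hz = c(10, 100)) {
  if (inherits(rec, "recording")) {
    v <- rec$v_mc
    t_ms <- rec$t_ms
  } else {
    v <- as.matrix(rec)
    t_ms <- seq_len(nrow(v))
  }
  if (!is.null(window_ms)) {
    keep <- t_ms >= window_ms[1] & t_ms <= window_ms[2]
    v <- v[keep, , drop = FALSE]
    t_ms <- t_ms[keep]
  }
  if (length(t_ms) < 2) stop("analysis window too short")
  fs_hz <- 1000 / (t_ms[2] - t_ms[1])
  raw <- rowMeans(v)
  list(t_ms = t_ms, slfp = bandpass_zerophase(raw, fs_hz, band_hz),
       raw = raw, fs_hz = fs_hz)
}

#' FFT power spectrum
#'
#' Power spectrum of a (typically already band-passed) signal.  The
#' demeaned signal is Hann-windowed and zero-padded to at least
#' `min_len_s` of effective length so that the native frequency bins are
#' no wider than ~0.6 Hz; the reported peak is refined by a quadratic fit
#' around the argmax.
#'
#' @param x signal.
#' @param fs_hz sampling rate (Hz).
#' @param min_len_s minimum effective (padded) length in seconds.
#' @return a list of class `spectrum_result`: `freq_hz`, `power`.
#' @export
power_spectrum <- function(x, fs_hz, min_len_s = 2) {
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_along(x) / (length(x) + 1))
  x <- x * w
  n <- max(length(x), ceiling(min_len_s * fs_hz))
  n <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, numeric(n - length(x))))
  half <- seq_len(n %/% 2)
  out <- list(freq_hz = (half - 1) * fs_hz / n,
              power = Mod(xf[half])^2 / length(x))
  class(out) <- "spectrum_result"
  out
}

#' Spectral peak frequency
#'
#' Argmax of the power spectrum over the analysis band, refined by a
#' quadratic (parabolic) interpolation of the three bins around the peak.
#' A spectrum whose maximum is less than `dominance` times the median
#' band power (after smoothing) is flagged as having no dominant peak;
#' the default threshold of 4 sits well above the ratios that pure-noise
#' periodograms reach in this band and far below those of genuine
#' oscillations.
#'
#' @param spec a `spectrum_result` from [power_spectrum()].
#' @param band_hz frequency band searched (default 10-100 Hz).
#' @param dominance dominance threshold (peak / median band power of the
#'   smoothed spectrum).
#' @param smooth_hz width of the moving-average smoothing applied before
#'   the argmax/dominance assessment; raw periodogram bins fluctuate too
#'   much for a meaningful peak/median ratio.
#' @return list with `freq_hz` (NA when not dominant), `power`,
#'   `dominant` (logical), `ratio` (peak / median power).
#' @export
peak_frequency <- function(spec, band_hz = c(10, 100), dominance = 4,
                           smooth_hz = 3) {
  df <- spec$freq_hz[2] - spec$freq_hz[1]
  w <- max(1L, round(smooth_hz / df))
  if (w %% 2 == 0) w <- w + 1L
  psm <- as.numeric(stats::filter(spec$power, rep(1 / w, w), sides = 2))
  psm[is.na(psm)] <- spec$power[is.na(psm)]
  sel <- which(spec$freq_hz >= band_hz[1] & spec$freq_hz <= band_hz[2])
  if (length(sel) < 3) stop("spectrum has no support in the band")
  p <- psm[sel]
  f <- spec$freq_hz[sel]
  k <- which.max(p)
  ratio <- p[k] / stats::median(p)
  if (!is.finite(ratio)) ratio <- if (p[k] > 0) Inf else 0
  freq <- f[k]
  if (k > 1 && k < length(p)) {
    # quadratic fit through the three bins around the argmax
    num <- p[k - 1] - p[k + 1]
    den <- p[k - 1] - 2 * p[k] + p[k + 1]
    if (den != 0) freq <- f[k] + 0.5 * num / den * (f[2] - f[1])
  }
  list(freq_hz = if (ratio >= dominance) freq else NA_real_,
       power = p[k], dominant = ratio >= dominance, ratio = ratio)
}

#' Locate peaks of an oscillatory trace
#'
#' Local maxima above a minimal prominence, used as the phase reference
#' (phase 0) of the sLFP cycle.
#'
#' @param x trace.
#' @param t_ms time base (ms).
#' @param min_height minimal height relative to the trace's standard
#'   deviation (default 0: all local maxima above the mean are accepted).
#' @param min_spacing_ms minimal spacing between accepted peaks; when two
#'   candidate maxima are closer, the higher one wins.  Use ~60% of the
#'   dominant oscillation period to suppress noise ripples.
#' @return times (ms) of the peaks.
#' @export
trace_peaks <- function(x, t_ms, min_height = 0, min_spacing_ms = 0) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  idx <- idx[x[idx] > mean(x) + min_height * stats::sd(x)]
  if (min_spacing_ms > 0 && length(idx) > 1) {
    ord <- idx[order(-x[idx])]
    keep <- logical(0)
    kept_t <- numeric(0)
    for (i in ord) {
      if (!length(kept_t) || all(abs(t_ms[i] - kept_t) >= min_spacing_ms)) {
        kept_t <- c(kept_t, t_ms[i])
      }
    }
    return(sort(kept_t))
  }
  t_ms[idx]
}

#' Times of the dominant-cycle peaks of an sLFP
#'
#' Identifies the dominant oscillation frequency of the filtered trace
#' and returns its cycle peaks (local maxima at least 60% of the dominant
#' period apart), the phase reference used for spike phases.
#'
#' @param lf result of [compute_slfp()].
#' @return list with `peak_t_ms`, `freq_hz`, `dominant`.
#' @export
slfp_peak_times <- function(lf) {
  pk <- peak_frequency(power_spectrum(lf$slfp, lf$fs_hz))
  f <- if (pk$dominant) pk$freq_hz else {
    # fall back to the band maximum so phases remain computable
    p2 <- peak_frequency(power_spectrum(lf$slfp, lf$fs_hz), dominance = 0)
    p2$freq_hz
  }
  spacing <- 0.6 * 1000 / f
  list(peak_t_ms = trace_peaks(lf$slfp, lf$t_ms, min_spacing_ms = spacing),
       freq_hz = pk$freq_hz, dominant = pk$dominant)
}

#' Convert spike times to sLFP phases
#'
#' A spike at time `t` falling between consecutive sLFP peaks `t_k` and
#' `t_{k+1}` is assigned the phase `2 pi (t - t_k) / (t_{k+1} - t_k)`;
#' a spike exactly at a peak has phase 0.  Spikes outside any
#' peak-bracketed interval are excluded and counted.
#'
#' @param spike_t_ms spike times (ms).
#' @param peak_t_ms sLFP peak times (ms), e.g. from [trace_peaks()].
#' @return list of class `phase_sample`: `phase` (radians in [0, 2 pi)),
#'   `n_excluded`.
#' @export
spike_phases <- function(spike_t_ms, peak_t_ms) {
  peak_t_ms <- sort(peak_t_ms)
  if (length(peak_t_ms) < 2) {
    out <- list(phase = numeric(0), n_excluded = length(spike_t_ms))
    class(out) <- "phase_sample"
    return(out)
  }
  k <- findInterval(spike_t_ms, peak_t_ms)
  ok <- k >= 1 & k < length(peak_t_ms)
  t0 <- peak_t_ms[k[ok]]
  t1 <- peak_t_ms[k[ok] + 1]
  phase <- 2 * pi * (spike_t_ms[ok] - t0) / (t1 - t0)
  out <- list(phase = phase %% (2 * pi), n_excluded = sum(!ok))
  class(out) <- "phase_sample"
  out
}

#' Synchronization (phase-locking) index
#'
#' Vector strength of the spike phases:
#' `kappa = (1/N) sqrt((sum sin phi)^2 + (sum cos phi)^2)`, which is 1
#' when all phases coincide and ~1/sqrt(N) for uniformly random phases.
#'
#' @param phases a `phase_sample` or a numeric vector of phases (radians).
#' @return kappa in [0, 1]; `NA` when there are no spikes (undefined,
#'   reported as missing rather than zero).
#' @export
synchronization_index <- function(phases) {
  phi <- if (inherits(phases, "phase_sample")) phases$phase else phases
  n <- length(phi)
  if (n == 0) return(NA_real_)
  sqrt(sum(sin(phi))^2 + sum(cos(phi))^2) / n
}

#' Oscillation index
#'
#' Peak sLFP spectral power per condition, normalized to the largest peak
#' power attained across the seed replicates of a reference (control)
#' condition, so the reference condition's best seed attains OI = 1.
#' Runs without a dominant spectral peak contribute their (low) band
#' maximum, not zero.
#'
#' @param peak_powers per-seed peak powers of the condition of interest.
#' @param reference_powers per-seed peak powers of the normalizing
#'   (control) condition; defaults to `peak_powers`.
#' @return mean normalized oscillation index (scalar).
#' @export
oscillation_index <- function(peak_powers, reference_powers = peak_powers) {
  if (length(reference_powers) < 1 || all(is.na(reference_powers))) {
    stop("no reference peak powers")
  }
  mean(peak_powers, na.rm = TRUE) / max(reference_powers, na.rm = TRUE)
}

#' Population firing rates, spike histograms and sLFP autocorrelation
#'
#' @param spikes list of per-cell spike-time vectors (ms).
#' @param window_ms two-element analysis window (ms).
#' @param bin_ms histogram bin width (default 5 ms; all spikes of the
#'   population are summed per bin).
#' @return list with `rate_hz` (per cell), `mean_rate_hz`, `hist` (counts
#'   per bin), `breaks_ms`.
#' @export
rates_and_histograms <- function(spikes, window_ms, bin_ms = 5) {
  if (diff(window_ms) <= 0) stop("empty analysis window")
  dur_s <- diff(window_ms) / 1000
  in_win <- lapply(spikes, function(s) s[s >= window_ms[1] & s < window_ms[2]])
  rate <- vapply(in_win, length, integer(1)) / dur_s
  breaks <- seq(window_ms[1], window_ms[2], by = bin_ms)
  if (breaks[length(breaks)] < window_ms[2]) breaks <- c(breaks, window_ms[2])
  all_t <- unlist(in_win, use.names = FALSE)
  counts <- if (length(all_t)) {
    tabulate(findInterval(all_t, breaks), nbins = length(breaks) - 1)
  } else integer(length(breaks) - 1)
  list(rate_hz = rate, mean_rate_hz = mean(rate),
       hist = counts, breaks_ms = breaks)
}

#' Normalized autocorrelation of a trace
#'
#' @param x trace.
#' @param fs_hz sampling rate (Hz).
#' @param max_lag_ms maximal lag (ms).
#' @return data.frame `lag_ms`, `acf`.
#' @export
trace_autocorrelation <- function(x, fs_hz, max_lag_ms = 250) {
  lag_max <- min(length(x) - 1, round(max_lag_ms / 1000 * fs_hz))
  a <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)
  data.frame(lag_ms = a$lag[, 1, 1] / fs_hz * 1000, acf = a$acf[, 1, 1])
}

#' Subthreshold (spike-clipped) power spectrum of a voltage trace
#'
#' Spikes are removed by clipping the trace at a ceiling a few mV above
#' the subthreshold envelope before computing the power spectrum; the
#' dominant 10-100 Hz peak of the clipped trace is the subthreshold
#' oscillation (STO) frequency.
#'
#' @param v_mv voltage trace (mV).
#' @param fs_hz sampling rate (Hz).
#' @param clip_mv clipping ceiling (mV); default -40 mV sits above the
#'   STO envelope and below spike threshold overshoot.
#' @param band_hz band searched for the subthreshold peak.
#' @return list with `freq_hz`, `power`, `spectrum`, `dominant`.
#' @export
subthreshold_spectrum <- function(v_mv, fs_hz, clip_mv = -40,
                                  band_hz = c(10, 100)) {
  v <- pmin(v_mv, clip_mv)
  spec <- power_spectrum(v - mean(v), fs_hz)
  pk <- peak_frequency(spec, band_hz)
  list(freq_hz = pk$freq_hz, power = pk$power, spectrum = spec,
       dominant = pk$dominant, ratio = pk$ratio)
}
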