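# Afferent drive: sigmoidal OSN odor input per glomerular column, plus
# uncorrelated Poisson background excitation delivered to every cell
# through AMPA-kinetics conductance jumps.

#' Sigmoidal OSN odor input current
#'
#' `I(t) = u0 + 0.5 (us - u0) [tanh(3 (t - t_orn) / r - 3) + 1]`, rising
#' smoothly from the pre-odor baseline `u0` (pure-air input) to the odor
#' steady state `us` around `t_orn + r`.
#'
#' @param t_ms time (ms); vectorized.
#' @param u0_na pre-odor baseline current (nA).
#' @param us_na steady-state odor current (nA).
#' @param r transition-rate parameter (default 100).
#' @param t_orn_ms odor onset time (ms).
#' @return input current (nA).
#' @export
osn_current <- function(t_ms, u0_na, us_na, r = 100, t_orn_ms = 0) {
  u0_na + 0.5 * (us_na - u0_na) * (tanh(3 * (t_ms - t_orn_ms) / r - 3) + 1)
}

#' Draw a random odor input pattern
#'
#' Each glomerular column receives an independent uniform draw of its
#' baseline `u0 ~ U(u0_lo, u0_hi)` and steady state `us ~ U(us_lo, us_hi)`.
#' The default bounds are u0 in (0.1, 0.2) nA and us in (0.2, 1.0) nA;
#' the `us` bounds are the quantities varied in the afferent-heterogeneity
#' sweeps.
#'
#' @param n_columns number of glomerular columns.
#' @param us_lo,us_hi bounds of the steady-state draw (nA); `us_lo < us_hi`.
#' @param u0_lo,u0_hi bounds of the baseline draw (nA).
#' @param r transition-rate parameter.
#' @param t_orn_ms odor onset (ms).
#' @return a data.frame with one row per column: `u0_na`, `us_na`, `r`,
#'   `t_orn_ms`.  Uses the current RNG state; seed externally.
#' @export
draw_odor_pattern <- function(n_columns,
                              us_lo = 0.2, us_hi = 1.0,
                              u0_lo = 0.1, u0_hi = 0.2,
                              r = 100, t_orn_ms = 500) {
  if (us_lo >= us_hi) {
    stop("odor steady-state bounds invalid: `us_lo` must be < `us_hi`")
  }
  if (u0_lo >= u0_hi) {
    stop("odor baseline bounds invalid: `u0_lo` must be < `u0_hi`")
  }
  data.frame(
    column = seq_len(n_columns),
    u0_na = stats::runif(n_columns, u0_lo, u0_hi),
    us_na = stats::runif(n_columns, us_lo, us_hi),
    r = r,
    t_orn_ms = t_orn_ms)
}

#' Homogeneous Poisson background event trains
#'
#' Generates independent event-time lists for `n_cells` cells at a common
#' rate.  Each event steps an AMPA-kinetics background conductance
#' (instantaneous rise, 5.5 ms exponential decay) on its target cell.
#'
#' @param rate_hz event rate per cell (Hz), >= 0.
#' @param duration_ms train duration (ms).
#' @param n_cells number of independent trains.
#' @return a list of `n_cells` numeric vectors of strictly increasing
#'   event times in (0, duration_ms).  Uses the current RNG state.
#' @export
poisson_background <- function(rate_hz, duration_ms, n_cells = 1) {
  if (rate_hz < 0) stop("`rate_hz` must be >= 0")
  lapply(seq_len(n_cells), function(i) {
    if (rate_hz == 0) return(numeric(0))
    n <- stats::rpois(1, rate_hz * duration_ms / 1000)
    sort(stats::runif(n, 0, duration_ms))
  })
}
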