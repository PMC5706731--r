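# Synaptic model: first-order channel gating driven by an instantaneous
# sigmoid of presynaptic voltage, with NMDA Mg2+ block on the postsynaptic
# side.  Excitatory (AMPA/NMDA) transmission is effectively spike-gated
# (half-activation at 0 mV, steep slope); GABA_A transmission is graded
# (half-activation at -40 mV, shallow slope), so inhibitory release tracks
# subthreshold presynaptic depolarization.

#' Construct a synapse specification
#'
#' Static parameters of one synapse type: maximal conductance, weight,
#' reversal potential, presynaptic activation sigmoid, and first-order
#' rise/decay time constants.
#'
#' Defaults by receptor class:
#' \describe{
#'   \item{AMPA}{g = 2 nS, E = 0 mV, theta = 0 mV, sigma = 0.2 mV,
#'     tau_rise = 1 ms, tau_decay = 5.5 ms}
#'   \item{NMDA}{g = 1 nS, E = 0 mV, theta = 0 mV, sigma = 0.2 mV,
#'     tau_rise = 52 ms, tau_decay = 343 ms, Mg block active}
#'   \item{GABA_A}{g = 2 nS, E = -80 mV, theta = -40 mV, sigma = 2 mV,
#'     tau_rise = 1.25 ms, tau_decay = 18 ms}
#' }
#'
#' @param kind one of `"AMPA"`, `"NMDA"`, `"GABA_A"`.
#' @param w dimensionless synaptic weight (>= 0); the effective maximal
#'   conductance is `w * g_syn_ns`.
#' @param g_syn_ns maximal synaptic conductance before weighting (nS).
#' @param e_syn_mv reversal potential (mV).
#' @param theta_mv half-activation voltage of the presynaptic sigmoid (mV).
#' @param sigma_mv slope of the presynaptic sigmoid (mV).
#' @param tau_rise_ms,tau_decay_ms first-order rise and decay time
#'   constants (ms); the channel opening/closing rates are their inverses.
#' @param mg_mm extracellular Mg2+ concentration (mM); only used for NMDA.
#' @return an object of class `synapse_spec`.
#' @export
synapse_spec <- function(kind = c("AMPA", "NMDA", "GABA_A"),
                         w = 1,
                         g_syn_ns = NULL,
                         e_syn_mv = NULL,
                         theta_mv = NULL,
                         sigma_mv = NULL,
                         tau_rise_ms = NULL,
                         tau_decay_ms = NULL,
                         mg_mm = 1) {
  kind <- match.arg(kind)
  def <- switch(kind,
    AMPA   = list(g = 2, e = 0,   th = 0,   sg = 0.2, tr = 1,    td = 5.5),
    NMDA   = list(g = 1, e = 0,   th = 0,   sg = 0.2, tr = 52,   td = 343),
    GABA_A = list(g = 2, e = -80, th = -40, sg = 2,   tr = 1.25, td = 18))
  spec <- list(
    kind = kind,
    w = w,
    g_syn_ns = if (is.null(g_syn_ns)) def$g else g_syn_ns,
    e_syn_mv = if (is.null(e_syn_mv)) def$e else e_syn_mv,
    theta_mv = if (is.null(theta_mv)) def$th else theta_mv,
    sigma_mv = if (is.null(sigma_mv)) def$sg else sigma_mv,
    tau_rise_ms = if (is.null(tau_rise_ms)) def$tr else tau_rise_ms,
    tau_decay_ms = if (is.null(tau_decay_ms)) def$td else tau_decay_ms,
    mg_mm = if (kind == "NMDA") mg_mm else 0)
  if (spec$w < 0) stop("synapse weight `w` must be >= 0")
  if (spec$g_syn_ns < 0) stop("`g_syn_ns` must be >= 0")
  if (spec$tau_rise_ms <= 0) stop("`tau_rise_ms` must be > 0")
  if (spec$tau_decay_ms <= 0) stop("`tau_decay_ms` must be > 0")
  if (spec$mg_mm < 0) stop("`mg_mm` must be >= 0")
  class(spec) <- "synapse_spec"
  spec
}

#' Presynaptic activation sigmoid
#'
#' Instantaneous fraction of transmitter drive as a function of presynaptic
#' membrane potential: `F = 1 / (1 + exp(-(V - theta) / sigma))`.
#'
#' @param v_pre_mv presynaptic membrane potential (mV); vectorized.
#' @param spec a [synapse_spec()].
#' @return activation in (0, 1).
#' @export
presynaptic_activation <- function(v_pre_mv, spec) {
  1 / (1 + exp(-(v_pre_mv - spec$theta_mv) / spec$sigma_mv))
}

#' NMDA magnesium block
#'
#' Voltage-dependent relief of the Mg2+ block of the NMDA receptor:
#' `B(V) = 1 / (1 + Mg * exp(-0.062 V) / 3.57)`.  AMPA and GABA_A synapses
#' are unblocked (`B = 1`).
#'
#' @param v_mv postsynaptic membrane potential (mV); vectorized.
#' @param spec a [synapse_spec()]; `spec$mg_mm` supplies the concentration.
#' @return block factor in (0, 1].
#' @export
mg_block <- function(v_mv, spec) {
  if (spec$kind != "NMDA" || spec$mg_mm == 0) return(rep(1, length(v_mv)))
  1 / (1 + spec$mg_mm * exp(-0.062 * v_mv) / 3.57)
}

#' Advance the synaptic gating variable by one timestep
#'
#' Integrates `ds/dt = alpha * F(V_pre) * (1 - s) - beta * s` with
#' `alpha = 1/tau_rise`, `beta = 1/tau_decay`, using the exact exponential
#' update under the assumption that `F` is constant over the step.  The
#' update is unconditionally stable and keeps `s` in [0, 1] for any `dt`.
#'
#' @param s current open fraction in [0, 1].
#' @param v_pre_mv presynaptic membrane potential held over the step (mV).
#' @param dt_ms timestep (ms), > 0.
#' @param spec a [synapse_spec()].
#' @return the open fraction after `dt_ms`.
#' @export
step_gating <- function(s, v_pre_mv, dt_ms, spec) {
  if (dt_ms <= 0) stop("`dt_ms` must be > 0")
  if (any(s < 0 | s > 1)) stop("gating variable `s` must lie in [0, 1]")
  alpha <- 1 / spec$tau_rise_ms
  beta <- 1 / spec$tau_decay_ms
  f <- presynaptic_activation(v_pre_mv, spec)
  rate <- alpha * f + beta
  s_inf <- alpha * f / rate
  s_inf + (s - s_inf) * exp(-dt_ms * rate)
}

#' Synaptic current
#'
#' `I = W * g_syn * s * B(V_post) * (V_post - E_syn)` in nA, with
#' conductance in nS and voltages in mV.  Positive current is outward
#' (hyperpolarizing by convention `C dV/dt = -I + ...`).
#'
#' @param s open fraction in [0, 1].
#' @param v_post_mv postsynaptic membrane potential (mV).
#' @param spec a [synapse_spec()].
#' @return current in nA (nS * mV * 1e-3... see Details).
#' @details Conductance nS times voltage mV yields pA; the value is
#'   returned in nA (i.e. divided by 1000) so that it is directly
#'   commensurate with the nA-scale afferent drive used elsewhere.
#' @export
synaptic_current <- function(s, v_post_mv, spec) {
  g_ns <- spec$w * spec$g_syn_ns * s * mg_block(v_post_mv, spec)
  g_ns * (v_post_mv - spec$e_syn_mv) / 1000
}
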