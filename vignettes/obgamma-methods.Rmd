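---
title: "Model and methods: an inhibition-coupled oscillator network of olfactory bulb gamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: an inhibition-coupled oscillator network of olfactory bulb gamma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Odor stimulation of the mammalian olfactory bulb evokes gamma-band
(30--80 Hz) local field potential oscillations that are broadly coherent
across the tissue, even though the principal neurons (mitral cells, MCs)
fire irregularly and at much lower rates than the population rhythm.
`obgamma` implements a biophysically explicit network model of this
phenomenon in which the gamma rhythm arises from a *pyramidal resonance
interneuron network gamma* (PRING) mechanism: MCs are intrinsic
subthreshold oscillators (~29 Hz when depolarized by 0.2 nA), and
granule-cell (GC) mediated graded dendrodendritic inhibition periodically
resets the phase of those subthreshold oscillations (STOs), coupling the
cellular oscillators into a common, faster network rhythm whose frequency
is governed by the GABA~A~ decay time constant.

The package exists so that every standard manipulation of this model --
removing the STO mechanism, speeding its kinetics, sweeping synaptic
weights, input bounds and GC population size -- is a named, reproducible,
seed-averaged scenario.

# Network architecture

* 25 MCs and 25 periglomerular cells (PGCs) form 5 x 5 grids of
  glomerular columns over a 1 mm x 1 mm sheet; 100 GCs form a 10 x 10
  grid over the same sheet (225 or 400 in the scaling scenarios).  The
  sheet is wrapped onto a torus, so distances have no boundary effects
  and the maximal separation is sqrt(2)/2 mm.
* Linear cell ids follow `z = N*i + j + 1` for grid position (i, j).
* Each MC forms a reciprocal dendrodendritic pair with its own column's
  PGC (MC tuft <-> PGC spine) and connects reciprocally to each GC
  independently with probability p = 0.3.  The MC-side contact sits on
  one of the seven lateral-dendrite compartments, chosen by partitioning
  the possible toroidal soma-to-GC distances into seven equal bins --
  the contact moves distally as the partner GC gets farther, which is
  the simplest deterministic, monotone reading of distance-dependent
  contact placement.
* Every GC spine hosts one excitatory postsynaptic site (AMPA + NMDA)
  and one graded GABAergic presynaptic site, so recurrent and lateral
  inhibition are contact-specific.

# Cell models

All three cell types are Hodgkin-Huxley-type compartmental models built
from cylindrical compartments (soma/body, spines, dendrites) with
Traub-style transient Na^+^ and delayed-rectifier K^+^ spike currents
and ohmic leak.  The mitral cell adds, at the soma:

* a persistent Na^+^ current `I_NaP = g_NaP * m_inf(v) * (v - E_Na)`
  with instantaneous sigmoidal activation,
* a slow K^+^ current `I_KS` with first-order activation (time constant
  `tau_KS` = 10 ms by default), and
* a slow spike-activated adaptation K^+^ current (high activation
  threshold, ~10^2^ ms relaxation).

The NaP/KS pair is the resonance mechanism: around a depolarized
operating point the fast regenerative NaP and the slow restorative KS
current form a damped or weakly self-sustained oscillator whose
eigenfrequency is ~29 Hz at 0.2 nA somatic injection.  The adaptation
current exists because the two-current mechanism alone produces either
tonic firing phase-locked 1:1 to the STO or a purely subthreshold
oscillation; a slow spike-triggered K^+^ conductance lets spikes ride
the STO crest only on a minority of cycles, reproducing the mixed-mode
firing (spike rates well below the STO frequency) that characterizes
mitral cells.  This is the package's own resolution of a gap in the
published cell-level description, and its consequences are confined to
spike timing: the STO frequency anchors (29 Hz default, 44 Hz with the
fast-kinetics variant) are calibrated with the adaptation current in
place.

Channel kinetics are fixed in the integrator; all densities, geometry
and sigmoid parameters live in the versioned plain-text parameter file
`inst/extdata/cell_params.yaml` and are validated on load.  The values
there were calibrated against the model's printed anchors:

* isolated MC, 0.2 nA somatic step: dominant subthreshold spectral peak
  at 29 Hz, with spikes sparser than STO cycles;
* fast-kinetics variant (`tau_KS` 10 -> 5 ms, `g_KS` x 1.6, `g_NaP` x
  1.3): subthreshold peak at 44 Hz with approximately unchanged firing
  rate;
* somatic spikes propagate to the distal (500 um) lateral-dendrite
  compartment at >= 80% amplitude in < 1 ms;
* STO frequency non-decreasing in injected current over 0.15-0.25 nA;
* replacing `I_NaP` by the ohmic cation current `I_CAT = 0.26 mS/cm^2 *
  (v - 0 mV)` abolishes the subthreshold spectral peak while preserving
  the f-I curve within ~15% over 0.1-0.3 nA;
* GC spontaneous rate ~1 Hz under background noise alone; PGC spiking
  not phase-locked to the network rhythm.

Granule cells are a compact body plus one spine per reciprocal contact
(spine neck ~1 nS); periglomerular cells are a body plus a single spine.
Their only active currents are the spiking Na^+^/K^+^ pair.

# Synapses

Synaptic currents follow `I = W * g_syn * s * B(V) * (V - E_syn)` with
first-order gating `ds/dt = alpha * F(V_pre) * (1 - s) - beta * s`,
where `F` is an instantaneous sigmoid of presynaptic voltage.
Excitatory synapses (AMPA: g = 2 nS, tau 1/5.5 ms; NMDA: g = 1 nS, tau
52/343 ms, Mg^2+^ block `B(V) = 1/(1 + [Mg] e^{-0.062V}/3.57)` with
[Mg] = 1 mM) half-activate at 0 mV with a 0.2 mV slope, so they are
effectively spike-gated.  GABA~A~ synapses (g = 2 nS, tau 1.25/18 ms,
E = -80 mV) half-activate at -40 mV with a 2 mV slope, so inhibitory
release is graded in the presynaptic subthreshold voltage -- the
mechanism that lets GC spines inhibit MC dendrites without GC somatic
spikes.  Default weights: W(MC->PGC) = 1, W(MC->GC) = 1, W(PGC->MC) = 4,
W(GC->MC) = 2.

The Mg^2+^ concentration is not part of the published parameter set; we
use the standard 1 mM convention for this block formula, configurable
per run.  The configuration key `tau_decay_gaba` changes the GC->MC
decay constant only (the quantity manipulated in the kinetics
scenarios); the PGC->MC synapse keeps its own default unless
`tau_decay_gaba_pgc` is set.  Gating uses the exact exponential update
for piecewise-constant `F` over one step, which is unconditionally
stable and keeps `s` in [0, 1] at any timestep.

# Inputs

Each column's OSN drive follows the sigmoid
`I(t) = u0 + 0.5 (us - u0) [tanh(3 (t - t_orn)/r - 3) + 1]` with
`r = 100`, `u0 ~ U(0.1, 0.2)` nA and `us ~ U(0.2, 1.0)` nA by default;
the input-bound scenarios move the `us` bounds.  The same current enters
the MC tuft and (scaled by a small configurable gain) the column's PGC
spine, implementing shared glomerular input with feedforward inhibition.
All 150 cells additionally receive uncorrelated Poisson trains of
AMPA-kinetics conductance steps (5.5 ms decay).  Neither the background
rate nor its amplitude is part of the published parameter set; the
defaults (14 Hz trains of 3.5 nS jumps on MC somata, 0.06 / 0.08 nS on
GC / PGC bodies) were calibrated once so that, with odor off, GCs fire
at ~1-2 Hz and MCs show sparse spontaneous spiking, while under odor
the uncorrelated drive decorrelates MC spike timing enough to give a
realistic (sub-unity) synchronization index.  Sparse-but-large events
were preferred over dense small ones because they deliver timing jitter
with little mean depolarization.

Default protocol timing (a declared choice, not a published one):
500 ms of pure-air baseline, odor onset at `t_orn` = 500 ms, odor held
to the end of the run; the analysis window is the odor epoch minus its
first 200 ms transient.

# Numerics

The integrator advances all compartments with a semi-implicit scheme:
the voltage step is backward-Euler along each cell's compartment tree
(Hines-ordered elimination, unconditionally stable for the linear
part), channel gates and synaptic gating use exact exponential updates,
and nonlinear coefficients (NaP activation, NMDA block, presynaptic
sigmoids) are evaluated at the current voltage.  Voltage-dependent rate
functions are tabulated per run on a 0.05 mV grid.  The default
timestep is 20 us (the reduced-cost profile used throughout the test
suite; the full profile uses 10 us, and the engine accepts arbitrary
`dt_ms`).  Timestep insensitivity is enforced by regression
tests: halving dt changes the isolated cell's STO frequency by < 1% and
its firing rate by < 2% (the non-chaotic configuration where
discretization error is actually measurable), and leaves seed-averaged
network firing rates within 2%.  Individual network trajectories are
chaotic, so spike-for-spike agreement across timesteps is neither
expected nor tested.  Spike detection is the somatic upward crossing
of 0 mV with a 2 ms lockout; traces are sampled at 0.5 ms (2 kHz),
ample for 10-100 Hz analysis.  Runs abort with a diagnostic if any
compartment leaves +-200 mV.

Seed policy: a master seed derives separate sub-streams for
connectivity, odor draws and background noise, so sweeps hold wiring
fixed while varying noise.  Identical (configuration, seed, dt) gives
bitwise-identical spike trains.

# Analysis

* **sLFP**: mean of the 25 MC somatic potentials, band-passed 10-100 Hz
  with a linear-phase FIR filter applied forward-backward (zero phase).
* **Spectrum**: Hann-windowed FFT of the filtered sLFP, zero-padded to
  >= 2 s so bins are <= 0.6 Hz, with a quadratic fit around the argmax
  of a lightly smoothed (3 Hz moving-average) spectrum.  A peak below
  four times the median band power of the smoothed spectrum is flagged
  "no dominant peak" instead of reported as a frequency; the threshold
  was chosen so that pure-noise periodograms (whose raw max/median
  ratios exceed 2 even after smoothing) are reliably flagged while
  genuine oscillations, whose ratios run in the hundreds, never are.
* **Spike phases**: each MC spike between consecutive sLFP peaks gets
  phase `2*pi*(t - t_k)/(t_{k+1} - t_k)` (0 at the peak/crest).  The
  synchronization index is the vector strength of those phases (Eq-4
  style kappa), undefined (reported missing) when there are no spikes.
* **Oscillation index**: mean sLFP peak power of a condition normalized
  to the maximum peak power across the control condition's seed set, so
  the control's best seed defines OI = 1 and OI is comparable across a
  sweep.
* **Rates/histograms**: per-cell spike counts over the analysis window;
  population histograms with 5 ms bins.

The surrogate generator builds `recording` objects with known ground
truth (a common sinusoidal "somatic" trace plus white noise; spike
phases drawn from a wrapped von Mises-like distribution by inverse-CDF
sampling), giving a monotone concentration -> kappa calibration curve.
Round-trip tests require the pipeline to recover frequency, rate and
locking strength across 20 random specifications.

# Known quantitative residuals

After calibration, the isolated-cell anchors are reproduced closely
(STO peaks 29.1 / 42.7 Hz for the default / fast variants; propagation
0.44 ms) and the control network sits near, but not on, the published
operating point: the sLFP peak centers at ~35.5 Hz (published 32.4),
mitral rates at ~10.7 Hz (published 14), granule rates at ~4.3 Hz
(published 4.6), SI ~0.71 (published 0.64).  Three manipulations are
reproduced qualitatively but not quantitatively: with fast-STO cells
and 3 ms inhibition the restored rhythm runs near ~38 Hz rather than
51 Hz (the fast cells skip spikes under network inhibition, weakening
the loop); fully disinhibited mitral cells run near ~58 Hz rather than
24 Hz (this implementation's f-I curve is steeper than the antecedent
model's, a consequence of prioritizing the exact subthreshold-frequency
anchors during calibration); and under eightfold excitatory weights the
rhythm slows below control rather than holding near it.  The acceptance
suite reports these discrepancies rather than masking them.

# What the simulations do and do not show

The synthetic odor is a static, heterogeneous input pattern: there is
no sniff-cycle modulation, receptor chemistry, cholinergic modulation
or cortical feedback, and the network is a ~150-cell caricature of a
structure with orders of magnitude more neurons (the GC-scaling
scenarios probe that axis specifically, with per-synapse conductance
renormalized by 100/N~GC~).  Passing tests therefore demonstrate the
internal consistency of the PRING mechanism under the stated
conditions -- not a fit to any particular recorded dataset.  Channel
kinetics are a standard parameterization calibrated to printed
spectral/rate anchors, not a reconstruction of the antecedent model's
equations, so trace-level agreement with that model is not claimed;
network-level quantities are reproduced within the looser tolerances
appropriate to a re-calibrated model.

# Scenario registry and profiles

`scenario_registry()` names every standard manipulation (control,
`sto_removed`, `sto_fast`, `sto_fast_gaba3`, `gaba3`, `gaba30`,
`gc_off`, `wgcmc3x`, `wgcmc3x_pgc_half`, `wmcgc8`, `wmcgc_half`,
`pgc_off`, `pgc_half`, `pgc_double`, `input_narrow`, `input_strong`,
`ngc_225`, `ngc_400`).  `run_scenario()` runs one scenario over a seed
set (connectivity fixed, noise varying) and reports per-seed and
seed-averaged metrics; `sweep_parameter()` varies one documented
configuration key with shared wiring.  The reduced-cost profile (the
default here: 5 seeds, 2 s runs with 1.5 s of odor, dt = 20 us) keeps a
full scenario batch to a few minutes on one CPU; the full profile uses
10 seeds, 3 s runs and dt = 10 us.  Problem sizes in the test suite and
the acceptance script use the reduced-cost profile.

A thin command-line front end (`scripts/obgamma`) exposes `run`,
`sweep`, `analyze`, `surrogate` and `list-scenarios` over these
functions.
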