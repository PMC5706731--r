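# Calibrated cell parameters for the olfactory-bulb network model.
# Units: lengths um; specific capacitance uF/cm2; conductance densities
# mS/cm2; potentials mV; time constants ms; spine neck conductance nS.
#
# Channel kinetics (Traub-style transient Na+ / delayed-rectifier K+,
# instantaneous-activation persistent Na+, first-order slow K+, slow
# shunting adaptation) are fixed in the integrator; the free values
# below were calibrated once against the model's anchors -- 29 Hz
# subthreshold-oscillation peak in an isolated mitral cell at 0.2 nA
# (44 Hz after the fast-kinetics modification), quiescence at rest,
# STO-frequency monotonicity in drive, cation-substitution f-I match,
# <1 ms dendritic spike propagation, ~1 Hz spontaneous granule-cell
# rate and 3-7 Hz odor-evoked granule firing -- and are not tuned
# per scenario.
version: 2
shared:
  e_na: 45.0
  e_k: -90.0
  ra_ohm_cm: 70.0
mc:
  # persistent Na+ (instantaneous activation) and slow K+ (first-order,
  # tau_ms) generate the subthreshold resonance
  nap: {theta_mv: -55.7531066, sigma_mv: 4.3175032}
  ks: {theta_mv: -55.530004, sigma_mv: 2.5641521, tau_ms: 10.0}
  # slow spike-activated adaptation conductance; its reversal sits near
  # the subthreshold operating point so it damps the oscillator without
  # displacing it (shunting rather than hyperpolarizing)
  adp: {theta_mv: -30.377563, sigma_mv: 5.0, tau_ms: 222.5878297, e_mv: -74.3972416}
  soma:
    l_um: 25.0
    diam_um: 20.0
    cm_uf_cm2: 1.2
    g_na: 68.5556384
    g_kdr: 11.4978655
    g_leak: 0.2438789
    e_leak: -68.3891101
    g_nap: 0.3447358
    g_ks: 1.4233023
    g_adp: 25.1142267
  tuft:
    l_um: 20.0
    diam_um: 10.0
    cm_uf_cm2: 1.2
    g_na: 20.0
    g_kdr: 10.0
    g_leak: 0.2438789
    e_leak: -68.3891101
    g_nap: 0.0
    g_ks: 0.0
  dend:   # replicated for the 7 lateral-dendrite compartments (500 um)
    n_comp: 7
    total_l_um: 500.0
    diam_um: 3.4
    cm_uf_cm2: 1.2
    g_na: 30.0
    g_kdr: 15.0
    g_leak: 0.2438789
    e_leak: -68.3891101
    g_nap: 0.0
    g_ks: 0.0
gc:
  # compact, high-impedance body; spike threshold tuned so granule
  # firing stays sparse relative to the network rhythm while graded
  # release from the spines persists
  body:
    l_um: 8.0
    diam_um: 8.0
    cm_uf_cm2: 1.0
    g_na: 6.2
    g_kdr: 3.1
    g_leak: 0.45
    e_leak: -73.672
  spine:
    l_um: 1.0
    diam_um: 1.0
    cm_uf_cm2: 1.0
    g_leak: 0.45
    e_leak: -73.672
    neck_g_ns: 1.0
pgc:
  # leaky body with strong direct OSN drive: periglomerular spiking is
  # dominated by the tonic afferent rather than the rhythmic MC input,
  # so it stays unlocked from the network oscillation
  body:
    l_um: 8.0
    diam_um: 8.0
    cm_uf_cm2: 1.0
    g_na: 40.0
    g_kdr: 20.0
    g_leak: 2.2
    e_leak: -70.0
  spine:
    l_um: 1.0
    diam_um: 1.0
    cm_uf_cm2: 1.0
    g_leak: 2.2
    e_leak: -70.0
    neck_g_ns: 1.0
  # fraction of the column's OSN current delivered to the PGC spine
  osn_gain: 0.07
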