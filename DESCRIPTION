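Package: obgamma
Title: Biophysical Simulation of Olfactory Bulb Gamma Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conductance-based network model of the mammalian olfactory bulb
    in which resonant mitral cells, granule cells and periglomerular cells
    interact through spike-gated excitation and graded dendrodendritic
    inhibition on a two-dimensional toroidal sheet. The package provides
    Hodgkin-Huxley-type compartmental cell models with persistent-sodium /
    slow-potassium subthreshold oscillations, first-order synaptic kinetics
    with NMDA magnesium block, a fixed-timestep semi-implicit network
    integrator, sigmoidal olfactory-sensory-neuron odor drive with Poisson
    background excitation, and an analysis suite (simulated local field
    potential, band-passed spectra, spike-phase synchronization and
    oscillation indices). A scenario registry reproduces the standard
    manipulations of the model: subthreshold-oscillation removal and
    kinetics changes, synaptic-weight and input-bound sweeps, and granule
    cell population scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
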