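Package: flagspike
Title: Modular Modelling of Calcium Spike Trains in Sea Urchin Sperm Flagella
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley style) modelling of the
    signalling network that converts sperm-activating peptide (SAP) stimuli
    into trains of intraflagellar calcium spikes in sea urchin sperm.  The
    package implements an upstream receptor/cGMP/KCNG/spHCN module and two
    alternative downstream oscillator modules (CaV+BK and CatSper+NHE),
    together with their weighted mixtures; closed-form derivation of the
    equilibrium-constrained parameters (leak reversal potential, calcium
    source rate, proton leak rate); stimulus, pH-clamp and voltage-pulse
    simulation protocols; spike-train quantification (spike times,
    amplitudes, interspike intervals, envelope regression slopes) with the
    associated physiological selection criteria; brute-force attractor
    analysis of the clamped-cGMP submodels; an evolutionary random-walk
    exploration of the mixed-scenario parameter space with conductance-plane
    clustering; least-squares fitting of the upstream module to bulk cGMP
    kinetics and early membrane-potential responses; and generators for
    synthetic fluorescence traces, cGMP dose-response datasets and
    constructed spike trains used as test oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
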