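Package: synrelease
Title: Dual Calcium-Sensor Kinetics and Phenomenological Models of
    Presynaptic Vesicle Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling neurotransmitter release at presynaptic
    terminals driven by intracellular calcium.  Implements deterministic
    state-probability propagation of the dual synaptotagmin (Syt-1/Syt-7)
    calcium-sensor scheme with a killing (vesicle fusion) state and
    per-step renormalization, yielding conditional (hazard) release
    rates; a phenomenological multi-exponential release-rate profile
    with ex-Gaussian onset-delay filters and multi-spike combination; a
    saturating multi-timescale facilitation function acting on component
    release fidelities; an event-driven stochastic sampler of release
    times; and fitting machinery (instantaneous time constants,
    FVU-based cost, Nelder-Mead optimization, ramp-probe stimulus
    protocols) to recover profile parameters and facilitation
    metaparameters from release-rate traces.  A synthetic calcium-trace
    generator emulates spike-evoked transients over a 100 nM baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
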