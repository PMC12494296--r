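Package: dopadyn
Title: Circadian and Ultradian Dynamics of Dopamine Synthesis, Release,
    and Reuptake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a reduced four-variable kinetic
    model of dopamine synthesis, vesicular packaging, release, and
    reuptake in a dopaminergic terminal, with sinusoidal circadian
    modulation of tyrosine hydroxylase and monoamine oxidase activity
    and exponentially decaying dopamine-reuptake-inhibitor (DRI)
    dosing.  Includes a six-variable extension (the Dopamine Ultradian
    Oscillator) in which feedback from pooled dopaminergic tone through
    D2 autoreceptor signalling generates intrinsic ultradian rhythms.
    Provides stiff integration with dose events, equilibrium solving,
    analytic Jacobians and linear stability maps, Hopf-bifurcation
    localization, dose-timing and half-life sweeps, homeostasis
    analyses, Latin hypercube parameter search, and trajectory summary
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
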