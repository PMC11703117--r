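Package: locustcompass
Title: Ring-Attractor Heading Circuit Model of the Desert Locust Central Complex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Firing-rate model of a heading (compass) circuit in the desert
    locust central complex. Steady-state rate neurons with slow dynamical
    synapses form a 34-unit network of CL1a and CL2 columnar neurons whose
    connectivity is constrained by anatomical masks; angular-velocity inputs
    act through multiplicative neuromodulation of synaptic conductances.
    Free synaptic weights are fitted by gradient-based optimisation (L-BFGS
    with a hand-derived adjoint gradient through the Runge-Kutta integrator).
    Includes evaluation suites for noise robustness of angular-velocity
    integration, ring-attractor stability, and a closed-loop walking-agent
    simulation coupled to a goal-directed steering circuit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
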