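Package: embsnn
Title: Desk-Scale Embodied Spiking Neural Network Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clock-driven spiking neural network kernel (leaky
    integrate-and-fire neurons with current- or conductance-based alpha
    synapses, power-law spike-timing-dependent plasticity, parrot relays,
    Poisson generators and spike recorders) together with the orchestration
    layers needed for embodied closed-loop experiments: a master-worker
    simulation-control server with response-combination heuristics, a
    closed-loop engine that advances brain and body in lockstep exchange
    windows and profiles every component, transfer functions between spike
    and muscle-activation domains, a simplified three-segment rodent
    forelimb with eight muscles and a two-degree-of-freedom joystick,
    constructors with exact dry-run censuses for a balanced random
    benchmark network and a multi-region cortico-basal
    ganglia-cerebellar-thalamic (CBCT) rodent brain model, and a
    benchmarking harness reporting real-time factor, brain/body step-time
    ratio and node-hours.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
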