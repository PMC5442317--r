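Package: spindlesim
Title: Brownian Dynamics-Kinetic Monte Carlo Simulation of
    Motor-Independent Mitotic Spindle Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates bipolar mitotic spindle assembly in a closed
    fission-yeast-like nucleus without molecular motors. Mobile spindle
    pole bodies in a fixed spherical nuclear envelope nucleate rigid
    microtubules undergoing force-dependent dynamic instability; passive
    antiparallel crosslinkers bind with partition-function-consistent
    kinetics, exert harmonic forces, diffuse along filaments, and locally
    stabilize microtubule dynamics near crosslinked plus ends. Includes a
    membrane wall-force model for protruding plus ends, a multi-filament
    Brownian-ratchet polymerization law, the interpolar-fraction
    bipolarity classifier, and random-sampling and single-parameter
    scans of the model's parameter space.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
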