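Package: ehgsim
Title: Forward Simulation of Electrohysterogram Surface Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulator of electrohysterogram (EHG) surface potentials.
    Implements a moving dipole-band model of the uterine depolarization front
    on a conical uterus wall, a quasi-static finite-difference volume-conductor
    solver for a layered hemispherical abdomen (skin, fat, muscle), and four
    surface-electrode read-out models: a monopolar disc and three Laplacian
    concentric-ring estimators (bipolar, quasi-bipolar and tri-polar), together
    with their five-point and nine-point finite-difference stencil oracles.
    Experiment drivers reproduce source-waveform recording, conduction-delay
    estimation, local-sensitivity (attenuation) sweeps with the 20 dB
    sensitivity distance, and fat/muscle tissue-thickness sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
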