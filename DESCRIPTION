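Package: fibrilmix
Title: Isoform Mixing Statistics of Amyloid Filaments from REDOR NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how two protein isoforms (such as 4R and 3R tau) mix
    along the axis of a parallel-in-register cross-beta amyloid filament. A
    two-state Markov copolymer model links nearest-neighbour transition
    probabilities to the stationary 4R mole fraction and a mixing quotient;
    a second-moment (Van Vleck) Gaussian forward model predicts 15N-13C
    REDOR dephasing curves from spin geometry and labeling statistics; a
    calibration-interpolation estimator extracts transition probabilities
    from measured dephasing curves with first-order error propagation;
    Monte-Carlo samplers generate isoform sequences under rejection
    criteria; and rigid-body helical replication builds long filament
    models annotated with simulated isoform sequences. A synthetic-data
    generator emulates calibration and mixed-label REDOR datasets so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
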