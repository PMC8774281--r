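Package: lysotraj
Title: Wavelet-Based Segmentation and Co-Movement Analysis of Intracellular Particle Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing intermittent ("stop-and-go") transport of
    organelles and their cargos from 2D single-particle tracking data.
    Implements continuous wavelet transform (Haar kernel) trajectory maps,
    universal-threshold detection of active-transport runs, error-radius
    merging of runs into flights, wavelet-correlation classification of
    organelle-cargo co-movement, mean-square-displacement scaling analysis,
    and maximum-likelihood comparison of heavy-tailed run/flight length
    models (lognormal, power law, truncated power law, stretched
    exponential, exponential) via Akaike weights. A seeded synthetic
    trajectory generator provides ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
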