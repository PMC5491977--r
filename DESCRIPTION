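Package: callosim
Title: Two-Column Neural Mass Model of Transcallosal Beta ERD/ERS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two four-population (Wendling-type) neural mass models
    of the right and left sensorimotor areas coupled by delayed excitatory
    transcallosal projections onto pyramidal cells and fast inhibitory
    interneurons. Generates beta-band rhythms under Gaussian driving noise,
    applies a smoothed-trapezoid modulating input emulating a motor-imagery
    trial, and quantifies the resulting event-related desynchronization and
    synchronization (ERD/ERS) of band power. Includes a fixed-step
    Euler-Maruyama integrator with a circular delay buffer, an algebraic
    fixed-point solver used as an independent oracle for population working
    points, modified-periodogram spectral estimation, coupling-strength sweeps
    with working-region classification, and a configuration-driven command
    line interface for reproducible seeded experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
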