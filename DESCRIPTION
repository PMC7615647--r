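Package: kymoquant
Title: Quantification of Single-Molecule Kymograph, Kinetics, and
    Force-Spectroscopy Data
Version: 0.1.0
Authors@R:
    person("Kymoquant", "Developers", email = "kymoquant@example.org",
           role = c("aut", "cre"))
Description: A reproducible analysis suite for dual-trap confocal
    single-molecule experiments on DNA tethers: sub-pixel particle
    tracking on kymographs, mean-square-displacement (MSD) diffusion
    analysis with motion classification, binding/nucleation kinetics and
    dwell-time fitting, photobleaching step counting for fluorophore
    stoichiometry, and extensible worm-like-chain (eWLC) force-extension
    analysis with rupture ("rip") detection.  A synthetic-data generator
    with known ground truth makes every stage verifiable by parameter
    recovery, so the pipeline can be validated without access to raw
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
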