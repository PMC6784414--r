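Package: stiflemorph
Title: Static Biomechanical Morphometry of the Marsupial Stifle
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes a static biomechanical profile of the marsupial stifle
    (the hindlimb knee) from triangle surface meshes, named anatomical
    landmarks and labelled muscle volumes: femoral and tibial segment
    lengths, knee flexion angle, extensor-mechanism moment arm about the
    transepicondylar axis, tibial plateau to tibial tuberosity plane metrics
    (TP:TT ratio and tuberosity projection index), quadriceps
    cross-sectional area with a volume proxy, and muscle pennation angles.
    Per-limb measurements are aggregated into median/range profile tables.
    A parametric synthetic hindlimb generator with analytically known ground
    truth supports end-to-end validation and landmark-noise sensitivity
    analysis.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
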