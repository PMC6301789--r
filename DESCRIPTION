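Package: plectoneme
Title: Sequence-Encoded Prediction of Plectoneme Pinning in Supercoiled DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts where plectonemes (the intertwined loops of supercoiled
    DNA) preferentially pin along a molecule, from sequence alone and without
    fitted parameters. The model reconstructs the intrinsic ground-state path
    of the double helix from dinucleotide tilt/roll/twist wedge parameters,
    measures intrinsic curvature and the preferred bend direction over
    candidate tip-loop windows, accumulates twist-rotated tilt/roll covariance
    matrices into a local direction-dependent persistence length, and converts
    tip-loop bending energetics into Boltzmann-weighted per-base plectoneme
    densities. Includes whole-genome scanning (linear or circular), bedGraph
    and TSV track export, strand-aware transcription-start-site meta-profiles,
    synthetic curved/flat fixture generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
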