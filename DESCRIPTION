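Package: cntselex
Title: Selection, Kinetics, and Machine-Learning Analysis of ssDNA Binders
    to Single-Walled Carbon Nanotubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing SELEX-style selection of single-stranded DNA
    sequences with high binding affinity to single-walled carbon nanotubes
    (SWCNTs). Includes simulators for selection rounds, surfactant-displacement
    kinetic traces and coarse-grained bead trajectories; round-over-round k-mer
    enrichment profiling of sequencing libraries; first-order time-constant
    fitting with censoring and 90-second affinity labelling; hydrogen-bond and
    near/far surface statistics plus mean-square-displacement curves for bead
    trajectories; and a binding-versus-random classification suite (random
    forest, multi-layer perceptron, convolutional, recurrent and attention
    networks) with transfer-learned affinity prediction and a
    composition-preserving sequence-shuffling ablation.
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
    jsonlite,
    minpack.lm,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
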