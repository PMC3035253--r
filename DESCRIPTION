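Package: gbdp
Title: Genome-to-Genome Distances for In-Silico DNA-DNA Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes genome-to-genome distances (GGD) from intergenomic
    high-scoring segment pairs (HSPs) or maximal unique matches (MUMs) under
    the ten GBDP distance functions, including the greedy-with-trimming
    overlap-removal algorithm and its coverage (no-trimming) variant.
    Provides parsers for BLAST tabular and MUMmer match lists, a built-in
    exact matcher so the pipeline runs without external aligners, an
    error-ratio-optimal distance threshold estimator that mimics the 70
    percent wet-lab DDH species boundary, rank/linear correlation and
    p-distance utilities for method evaluation, and a Lander-Waterman
    simulator of incompletely sequenced genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
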