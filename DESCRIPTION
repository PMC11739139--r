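Package: retroHTT
Title: Horizontal Transfer and Recombination Inference for LTR Retrotransposon Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect horizontal transposon transfer (HTT) and
    inter-subfamily recombination of LTR retrotransposons across closely
    related host strains. Implements coverage-based copy-number estimation for
    LTR and internal regions, structural classification of annotated copies
    (full-length, truncated, solo LTR) with defragmentation and a
    divergent-element rescue path, strain-specific majority-rule consensus
    building with depth/breadth quality control, Kimura 2-parameter
    sliding-window divergence profiling with recombination breakpoint calling,
    distance-based phylogenetics (NJ/BIONJ, midpoint rooting, bootstrap) with
    host-versus-element tree discordance flags, and a forward simulator of
    transposable element family evolution that provides truth-labelled inputs
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    IRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
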