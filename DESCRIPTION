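Package: chromocast
Title: Simulation and Detection of Chromothripsis and Other Catastrophic
    Genome Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying catastrophic DNA rearrangement processes in
    cell-line and tumor genomes. Provides a genome rearrangement simulator with
    exact ground truth (chromothripsis, breakage-fusion-bridge cycles,
    whole-genome doubling, simple structural variants), an emulator of the three
    observable sequencing layers (low-pass read depth, mate-pair junction calls,
    phased allele counts), circular binary segmentation of binned read depth
    with integer copy-number calling, the three-criterion chromothripsis caller
    with temporal ordering relative to BFB cycles and hyperploidization,
    haplotype-specific copy-number estimation from phased allelic ratios, and
    cohort-level association statistics (exact Fisher, Welch t, permutation and
    exact multinomial tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
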