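Package: mitorecomb
Title: Repeat Discovery and Recombination Analysis for Circular Organelle Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dispersed repeats and repeat-mediated
    recombination in circular (typically plant mitochondrial) genomes.
    Discovers repeats by seed-and-extend self-alignment with affine gap
    scoring and Karlin-Altschul E-value filtering, computes non-redundant
    repeat coverage and size-class statistics, predicts recombinant genome
    configurations across direct and inverted repeats together with the PCR
    assays that would detect them, detects chimeric reads supporting
    recombinant junctions, simulates PCR-mediated (in vitro) recombination
    across shared sequence regions as an artifact control, and produces
    mutually exclusive genome-content partition reports. A synthetic-data
    module generates circular genomes with planted repeats, recombinant
    molecule pools, and labelled read sets so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
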