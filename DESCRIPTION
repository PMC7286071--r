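Package: epitree
Title: Ancestral Reconstruction of Histone Modification States on Cell-Type Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-branch gain/loss histories of histone
    modifications and ancestral (progenitor) epigenomic states on a
    cell-type differentiation tree from multi-sample ChIP-seq peak tracks.
    Peaks are encoded as per-nucleotide binary ON/OFF characters, losslessly
    compressed into weighted site patterns, and analysed with undirected
    equal-cost Fitch parsimony under monophyly and backbone constraints,
    with ACCTRAN/DELTRAN resolution of ambiguous reconstructions. Inferred
    changes are annotated by distance to transcription start sites, tested
    for gene-set over-representation with Benjamini-Hochberg control, and
    integrated across modifications into per-gene chromatin-state calls
    (active, bivalent) at progenitor nodes. A fully specified synthetic-data
    generator with ground truth makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
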