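Package: methex
Title: Gene-Body DNA Methylation, Knockdown Simulation and
    Methylation-Expression Association for Insect WGBS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing whole-genome bisulfite sequencing (WGBS)
    count data from insects with sparse gene-body CG methylation: weighted
    methylation levels from allc-style cytosine count tables, bisulfite
    non-conversion estimation from an unmethylated spike-in, CpG dyad
    pairing and strand-symmetry summaries, genomic-compartment levels,
    binomial classification of genes as CG-methylated versus unmethylated
    with Benjamini-Hochberg correction and a false-negative drop rule,
    proportional-window metaplots over gene and transposable-element
    bodies, expression summaries (CPM filtering, FPKM, log2 fold-change,
    TE locus collapsing and RPKM), and association analyses relating
    methylation change to expression change (deciles, regression,
    delta-delta binning, overlap partitions). Includes a synthetic-data
    generator that emulates a maintenance-methyltransferase knockdown as a
    cell-mixture dilution of methylation, for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
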