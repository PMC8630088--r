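Package: epigain
Title: Spontaneous Epiallele Formation Analysis for Arabidopsis epiRIL Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying spontaneous hypermethylated epiallele formation
    from whole-genome bisulfite sequencing of epigenetic recombinant inbred
    lines (epiRILs). Classifies genes into gene-body methylated (gbM),
    transposon-like methylated (teM) and unmethylated (UM) states with per-gene
    binomial tests against coding-sequence background rates; calls per-cytosine
    methylation with a binomial test against the bisulfite non-conversion rate;
    reconstructs epiRIL parent-of-origin haplotypes from differentially
    methylated region (DMR) markers and computes the hypomethylation index;
    calls ectopic CHG/CWA methylation gains and their enrichment by gene class;
    maps methylation QTL by Haley-Knott interval mapping on a DMR-marker
    linkage map with permutation thresholds; quantifies 3D-contact enrichment
    between genes and H3K9me2 regions from significant Hi-C contacts; and
    includes a synthetic-data generator that emits every pipeline input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
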