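Package: methylRDA
Title: Redundancy Analysis Testing of Differential Methylation in Target
    Genomic Regions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests whether a target genomic region of any size is
    differentially methylated with respect to one or more outcome
    variables using redundancy analysis (RDA), a constrained ordination
    that regresses the M-values of all CpGs in the region on a design
    matrix and summarises the association with an R-squared and RDA
    components. Inference is by a label-permutation pseudo-F test and by
    an empirical genome-wide null that compares the region R-squared to
    random regions with the same number of CpGs. Includes a
    Beta-distribution simulator of 450K-style array data for power and
    type-I-error benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
biocViews: DNAMethylation, DifferentialMethylation, MethylationArray,
    Epigenetics, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
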