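Package: mtHaploDx
Title: Mitochondrial SNP Haplogroup Classification and Match-Ratio Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for associating study classes (disease patients,
    centenarians) with mitochondrial DNA haplogroups and for an initial
    haplogroup-based diagnosis from a person's mtDNA mutations. Implements
    a radial basis function (RBF) network over numerically encoded mtSNP
    genotype matrices, probability-ranked selection of top individuals
    ("modified clusters"), per-position nucleotide summaries, haplogroup
    assignment by defining-SNP profile matching, and a match-ratio
    diagnostic statistic with a configurable decision threshold. Ships
    eight haplogroup defining-SNP profile tables and a seeded cohort
    simulator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Classification, SNP, Genetics, MitochondrialDisease
RoxygenNote: 7.3.3
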