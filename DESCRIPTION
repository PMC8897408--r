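Package: museopop
Title: Genotype-Likelihood Population Genomics for Museum-Specimen Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for population-genomic inference from degraded,
    low- to medium-coverage whole-genome resequencing of historical (museum)
    specimens. Provides a structured-coalescent simulator with post-mortem
    deamination damage for parameter-recovery testing; GATK-model genotype
    likelihoods with EM allele-frequency estimation, likelihood-ratio SNP
    calling and a depth/missingness/MAF filter cascade; IUPAC consensus
    building, windowed alignments, uncorrected p-distances and mutation-rate
    scaled divergence dating; neighbor-joining window trees with bootstrap
    support and topology weighting; ABBA-BABA (Patterson's D) tests with
    weighted block-jackknife significance; windowed Weir-Cockerham Fst outlier
    scans; and genotype-likelihood PCA plus admixture estimation with Evanno
    DeltaK model choice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
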