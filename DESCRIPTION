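Package: PoolBSA
Title: Bulked Segregant Analysis Mapping of Recessive Loci from Pooled
    Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps recessive mutant loci from phenotype-pooled sequencing of
    F2 populations. Computes per-site SNP-index and delta SNP-index from
    pooled allelic depths, calls candidate intervals by threshold, narrows
    intervals by counting recombinant individuals at flanking markers,
    predicts and tests Mendelian segregation ratios for one- and two-locus
    crosses including the complementation (allelism) test, and implements
    standard phenotyping calculators (photosynthetic pigment contents from
    absorbance, chlorophyll-fluorescence parameters, and 2^-ddCt relative
    expression). A forward simulator of EMS-mutagenised F2 populations
    under the Haldane meiosis model generates pooled read counts, marker
    genotypes and phenotyping records with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Genetics, VariantDetection, Sequencing, Software
RoxygenNote: 7.3.3
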