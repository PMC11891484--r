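Package: popgenload
Title: Population Genetic Diversity, Inbreeding and Genetic Load from SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for conservation-genomic analysis of multi-sample SNP
    panels: variant filtering and ancestral-allele polarization, windowed
    nucleotide diversity and Tajima's D, Weir-Cockerham FST, individual
    inbreeding coefficients, linkage-disequilibrium decay, PLINK-style
    runs-of-homozygosity detection with F_ROH summaries, KING-robust
    pairwise kinship with relationship-degree classification, coding-effect
    annotation with Grantham-distance radical-missense calling,
    derived-allele genetic-load statistics including the purging-efficiency
    ratio R_p, Watterson-theta effective population size estimation, and a
    Wright-Fisher forward simulator with selection classes and pedigrees
    that generates fully reproducible test panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, SNP, VariantAnnotation, Genetics
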