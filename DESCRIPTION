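Package: breedtrace
Title: Selective Sweeps, Pedigree Haplotype Tracing and Selection
    Simulation for Elite Crop Breeding Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic history of long-term
    pedigree breeding programs in inbred crops. Computes sliding-window
    nucleotide diversity statistics (pi, Watterson's theta, Tajima's D)
    and calls selective-sweep blocks; detects linkage-disequilibrium
    haplotype blocks and traces their origin through the pedigree flow of
    recurrent-parent by donor crosses, calling blocks conserved across
    multiple sequential breeding generations; estimates original and
    corrected phenotypic variance explained (PVE) for QTLs and classifies
    trait architectures; and runs a forward-time artificial-selection
    simulator with a sigmoidal PVE-to-selection-probability map to explore
    how population size, heritability and mutation rate bound what
    phenotype-based breeding can achieve. A synthetic pedigree, genotype
    and phenotype generator makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
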