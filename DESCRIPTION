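Package: bsrqtl
Title: Linkage Mapping and Bulked Segregant RNA-Seq Dissection of Sporadic Traits in RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic dissection of sporadic, incompletely
    penetrant traits in biparental recombinant inbred line (RIL)
    populations. Provides phenotype statistics (replicate correlations,
    coefficient of variation, variance components, broad-sense
    heritability, per-line BLUPs), a genome-wide single-marker LOD scan
    with permutation thresholds and 1.5-LOD support intervals, a
    delta-SNP-index bulked segregant analysis with depth and index
    filters, sliding-window smoothing and a permutation-based 99% cutoff,
    and an integration step that intersects linkage and bulked-segregant
    regions, counts genes, classifies variants relative to gene models
    and filters candidates by expression. A synthetic-data module
    simulates RIL genotypes, sporadic seedling-count phenotypes with
    planted QTLs, extreme phenotypic bulks and pooled allele depths, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
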