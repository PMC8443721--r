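Package: clonalscape
Title: Heterozygosity Landscapes, Diversity Scans and GWAS Consensus for
    Clonal Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of clonally propagated
    plant populations from multi-sample SNP genotype data. Computes
    site- and window-level heterozygous-genotype frequencies and detects
    long continuous heterozygous regions (LCHRs); windowed nucleotide
    diversity (theta-pi, Watterson's theta), Tajima's D, Weir-Cockerham
    F_ST and outgroup-polarized derived allele frequencies; identity-by-state
    and Hamming genetic distances, lowest-quantile relatedness networks and
    Mantel tests of isolation by distance; a multi-method GWAS consensus
    procedure with marker-trait-association merging, gene assignment and
    hypergeometric enrichment; and divergence-based mutation-rate
    estimation. A synthetic clonal-population generator with known ground
    truth (planted LCHRs, somatic and founder heterozygosity classes, group
    structure, causal SNPs, correlated environmental factors) makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
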