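Package: refdivsim
Title: Simulating Reference Genome Divergence Effects on SNP Discovery and
    Diversity Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation pipeline for assessing how the phylogenetic distance of
    a reference genome affects SNP discovery and conservation-relevant
    diversity estimates. Generates a pedigreed diploid population on a focal
    genome, derives diverged references at congeneric, confamilial and
    conordinal substitution distances, simulates genotyping-by-sequencing
    (ApeKI) tag pairs and paired-end resequencing reads, maps them with a
    deterministic seed-and-extend aligner, calls SNPs tag-wise (among-tag
    differences) and by read-versus-reference pileup, applies the standard
    filter cascades (biallelic, minor allele frequency, depth, missingness,
    linkage-disequilibrium pruning, distance thinning), and computes
    nucleotide diversity, individual heterozygosity and a depth-aware genomic
    relatedness matrix with diagonal rescaling, together with tag-set
    intersection comparisons, Spearman rank correlations and Mantel
    permutation tests across references.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    VariantAnnotation,
    GenomicRanges,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
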