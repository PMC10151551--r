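Package: vinekin
Title: Kinship, Descent and Berry-Color Inference for Sparse Grapevine Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relatedness analysis of diploid biallelic SNP genotype
    panels with ancient-DNA-style sparsity, as used to connect archaeological
    grape pips to modern Levantine cultivars. Implements dataset construction
    filters (call rate, read depth, minor allele frequency) with a dual-dataset
    strategy trading SNP count against low-coverage sample count; the
    KING-robust heterozygote-concordance kinship estimator with IBS0 and
    relatedness classification; IBD-segment sharing matrices with heatmap
    sample orderings; a directional genotype-containment test with an error
    allowance for parent-offspring and selfing descent; a heterozygosity-ratio
    estimator of selfing generations; and additive polygenic berry-color
    scoring with reference-panel percentile placement. A pedigree simulator
    (outcrossing, selfing, cloning, genotyping error, missingness, phased
    haplotypes with founder-ancestry tracking) provides ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
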