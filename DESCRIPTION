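Package: milletgp
Title: Genomic Prediction and Domestication Scans for Pearl Millet Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics toolkit for pearl millet style breeding and
    diversity panels. Implements genomic best linear unbiased prediction
    (G-BLUP) with a VanRaden-type genomic relationship matrix, additive plus
    dominance ridge-regression BLUP for single-cross hybrid prediction and
    heterotic-group discovery, a windowed wild-versus-cultivated selection
    scan (nucleotide diversity, Watterson's theta, Tajima's D, Hudson's FST,
    log diversity-ratio outliers), linkage-disequilibrium decay, principal
    components and neighbour-joining trees from allele-sharing distances,
    EM-REML variance components with line-mean and broad-sense heritability,
    single-marker association scans with Benjamini-Hochberg control, and
    k-mer based genome-size estimation. A synthetic-data generator produces
    genotype, hybrid and multi-environment trial data with known truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    lme4,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
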