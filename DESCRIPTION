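Package: wolbshift
Title: Wolbachia Strain Detection, Sharing Statistics, Divergence Dating
    and Reproductive-Manipulation Locus Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying endosymbiont (Wolbachia) strain dynamics in
    host whole-genome resequencing data. Implements fragment-based average
    nucleotide identity (ANI) and greedy genome dereplication, competitive
    read mapping with iterative strain assignment driven by breadth of
    coverage and heterozygous-site density, consensus calling, permutation
    tests of strain sharing between host sister-species pairs with empirical
    p-values, a Bayesian logistic model of sharing with pMCMC summaries,
    Jukes-Cantor divergence dating of symbiont and mitochondrial splits
    against host split times with range-overlap congruence classification,
    a symbiont turnover-rate estimator, and a filter pipeline that screens
    homology hit tables for cytoplasmic-incompatibility (cifA/cifB) operons
    and male-killing (wmk) candidate loci. A synthetic-data generator with
    full ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
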