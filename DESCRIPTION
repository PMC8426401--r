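Package: pleiomix
Title: Polygenic Overlap and Conjunctional FDR Analysis of GWAS Summary
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cross-trait polygenic overlap from GWAS summary
    statistics with a bivariate causal (point-normal) mixture model fitted
    by characteristic-function likelihood of signed z-scores, visualises
    cross-trait enrichment with conditional Q-Q plots, discovers jointly
    associated variants with the conditional and conjunctional false
    discovery rate (condFDR/conjFDR) method using random-pruning-averaged
    stratified empirical cdfs, and defines genomic loci FUMA-style
    (independent significant, lead and candidate SNPs; merged locus
    intervals; effect-direction concordance). Ships an LD block-panel
    representation with LD scores, random pruning and greedy clumping, an
    LD-score-regression genetic correlation estimator with block-jackknife
    errors, and a synthetic bivariate GWAS generator with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
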