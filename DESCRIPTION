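Package: ayescan
Title: Simulation-Calibrated Genome Scans for Selective Sweeps and Balancing Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composite-likelihood-ratio (CLR) genome scans for recent selective
    sweeps and long-term balancing selection on folded allele-frequency data
    from small population samples, with null thresholds calibrated by
    simulation of a neutral demographic baseline. Includes an SMC' coalescent
    simulator for piecewise-constant demographies, a forward Wright-Fisher
    simulator with a discretized distribution of fitness effects, per-kilobase
    mutation and recombination rate heterogeneity and sweep or
    frequency-dependent balancing scenarios, threshold calibration and
    candidate annotation against gene and structural-variant intervals, and
    ROC-based power analysis. Developed around the study design used for
    population-level scans of the aye-aye (Daubentonia madagascariensis)
    genome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
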