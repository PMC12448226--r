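Package: hzclines
Title: Hybrid Zone Genomic and Geographic Cline Analysis with Tension-Zone Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for avian hybrid zones sampled along geographic
    transects. Provides Bayesian hybrid-index estimation from species-diagnostic
    SNP panels, per-locus Bayesian genomic cline fitting (steepness and centre),
    geographic cline fitting with exponential introgression tails by
    Metropolis-Hastings, Weir-Cockerham F_ST (per SNP and in sliding windows),
    per-individual inbreeding coefficients, mitotype assignment, detection of
    large chromosomal inversions from local PCA association score tracks, a
    forward-time stepping-stone tension-zone simulator with a moving
    environmental boundary, and cross-transect introgression-outlier reporting.
    A synthetic-data generator emulates two parental panels, admixed transect
    samples along a sigmoid ancestry cline, an mtDNA haplotype system and a
    recombination-suppressed Z-linked inversion block, so the whole pipeline is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
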