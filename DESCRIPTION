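Package: sweeplight
Title: Selective Sweep Detection and Selection-Experiment Inference for
    Light-Environment Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic toolkit for detecting selective sweeps at
    linked cone-opsin loci and quantifying their reversal in transplant
    experiments. Implements haplotype-based sweep statistics (EHH, iHS with
    frequency-bin standardization, window-iHS, H12), windowed diversity
    statistics (nucleotide diversity, Tajima's D, Hudson FST, LD r2),
    recombination-binned empirical-quantile outlier calling, MAF-binned
    allele-frequency-change quantiles, codon-level divergence (NG86 pairwise
    dN/dS, sliding synonymous divergence, spectral key-site classification,
    minimum-spanning haplotype networks), genotype-environment association
    via per-gene MDS coordinates and general linear models, evolutionary-rate
    (haldanes) and selection-coefficient estimation with a forward
    Wright-Fisher validation simulator, and a synthetic-data generator that
    emulates a multi-lake adaptive radiation and a source/transplant
    selection experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    vcfR,
    ape,
    igraph,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
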