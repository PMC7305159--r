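Package: histocc
Title: Chromatin Co-Occupancy Analysis with Spike-In Normalized ChIP Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing genome-wide co-occupancy of chromatin
    proteins and histone post-translational modifications from ChIP-seq,
    ChIP-Rx (exogenous spike-in), MNase-seq and whole-genome bisulfite data.
    Implements RPM and reference-adjusted (RRPM) spike-in normalization,
    binned genome-wide correlation, strand-aware aggregate (metagene)
    profiles, three-way nucleosome/protein occupancy classification with
    per-context methylation comparison, differential-enrichment difference
    classes with paired rank testing, sliding-window differentially
    methylated region detection, permutation-based region-association
    z-scores, multi-layer self-organizing-map (SuperSOM) clustering of
    TSS-proximal signal, and gene-set enrichment running-sum scores. A
    synthetic-data generator with planted ground truth (correlated
    log-normal mark intensities under Poisson read noise, planted overlap
    fractions, context-dependent methylation, cluster-structured
    TSS-proximal signal, spike-in global scaling) makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
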