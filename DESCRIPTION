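Package: nucarch
Title: Quantitative Nuclear Architecture Analysis After Cohesin Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements, on synthetic data with exported ground truth, the
    quantitative analyses used to characterize nuclear compartmentalization in
    cohesin-depleted cells: hidden Markov random field classification of DAPI
    voxel intensities into seven chromatin-compaction classes (equal-variance
    Gaussian mixture coupled by a Potts spatial prior), marker
    enrichment/depletion profiles over compaction classes, 3D segmentation and
    statistics of pulse-labeled replication domains, DNA-halo loop-size
    quantification, degradation-kinetics trace filtering, and Hi-C/Repli-Seq
    compartment analyses (KR balancing, observed/expected and Pearson maps,
    compartment eigenvector, histone-mark k-means clusters, between-cluster
    contact ratios, aggregate peak analysis, replication-timing preservation).
    Every input is produced by seeded synthetic-data generators so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
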