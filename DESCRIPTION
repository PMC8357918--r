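Package: megconsist
Title: Longitudinal Consistency of Source-Space MEG Spectra and Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-system resting-state MEG cohorts with
    subject-specific spectral and envelope-coupling fingerprints, reconstructs
    source activity at 90 atlas centroids with a scalar minimum-variance
    (LCMV) beamformer in a spherical head model, computes area-normalized
    power spectra and leakage-corrected amplitude envelope correlation
    (AEC-c) connectivity per frequency band, and quantifies within- and
    between-subject consistency of these source-space measures across
    recording sessions and sensor systems (Kolmogorov-Smirnov spectral
    distance, Spearman matrix correlation, repeated-measures ANOVA and
    t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, grDevices, graphics, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
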