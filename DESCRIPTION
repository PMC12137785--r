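Package: ptxRepro
Title: Longitudinal Reproducibility of Parallel-Transmit kT-Points Cardiac
    Excitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the session-to-session reproducibility of
    parallel-transmission (pTx) radiofrequency excitation of the human heart.
    The package simulates 8-channel complex transmit (B1+) field maps of a
    torso across subjects, scan sessions and MR operators; designs phase-only
    shim, subject-tailored and universal kT-points pulses with a
    magnitude-least-squares variable-exchange solver and interleaved greedy
    selection of transmit k-space locations; predicts flip-angle maps with the
    small-tip-angle model and a hard-pulse Bloch simulator; and quantifies
    flip-angle homogeneity reproducibility across scan groups with CV-space
    cluster statistics (inertia, centroid norm, perpendicular distance to the
    identity line) and paired Wilcoxon signed-rank tests with Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
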