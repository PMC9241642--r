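Package: trophomics
Title: Trophic-Position Estimation and Time-Course Metabolomics for a
    Bacterium-Nematode-Insect Food Web
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compound-specific nitrogen isotope (delta-15N of glutamic acid
    and phenylalanine) trophic-position estimation for entomopathogenic
    nematode-bacterium-insect food webs, together with a time-course
    metabolomics workflow: insect-weight normalization, log transformation
    and pareto scaling, PLS-DA with variable-importance-in-projection (VIP)
    scoring, Spearman-rank-distance hierarchical clustering of metabolite
    trajectories, phase-wise log rate-of-change profiling, per-metabolite
    significance testing, and a microarray-style fold-change filter. A
    synthetic-data generator with known ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
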