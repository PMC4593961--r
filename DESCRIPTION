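Package: semgmap
Title: Spatial Activation Mapping for High-Density Surface EMG
Version: 0.1.0
Authors@R:
    person("EMG", "Toolbox Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-density surface electromyography
    (HD-sEMG) grid recordings of forearm muscles. Builds electrode-grid
    models in relative forearm coordinates (% length, % circumference),
    preprocesses multichannel EMG with zero-phase Butterworth band-pass
    filtering, constructs baseline-corrected root-mean-square (RMS)
    activation maps, and quantifies spatial activation with the
    amplitude-weighted map centroid and a normalized sum-of-squared-difference
    (SSD) map-contrast statistic. Includes repeated-measures ANOVA with
    Mauchly sphericity testing and Greenhouse-Geisser correction, Tukey
    post hoc comparisons, a synthetic generator of compartmentalized
    multichannel EMG with full ground truth, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
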