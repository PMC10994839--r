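Package: stressmix
Title: Multiplicative-Null Interaction Analysis for Multi-Stressor
    Bacterial Growth Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how bacterial growth responds to all
    combinations of chemical stressors assayed on plate readers.
    Growth curves are summarised by spline-fitted area under the curve
    (AUC), converted to relative growth against no-chemical controls,
    and compared with a multiplicative (Bliss-type) null model over
    the full subset lattice of chemical mixtures.  Net and emergent
    (higher-order) interaction coefficients are estimated in log
    space, classified into antagonism or synergism by a two-stage
    percentile bootstrap, and summarised by mixture complexity.
    Response fingerprints can be tested for phylogenetic signal with
    a Kendall Mantel test, Pagel's lambda and Blomberg's K.  A
    synthetic plate-experiment generator with planted effects
    provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
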