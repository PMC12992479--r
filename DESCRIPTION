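Package: bireach
Title: Simulation and Analysis of Bimanual Reaching Interference Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates four-group bimanual reaching experiments in which the
    right hand is exposed to a visuomotor rotation, a velocity-dependent curl
    force field, both, or neither, while the unseen left hand is probed for
    interlimb interference, including force-channel catch trials. Extracts the
    standard per-trial kinematic error measures (normalized RMSE, initial
    directional error, initial endpoint error, final endpoint error), analyzes
    lateral wall forces on channel trials, and runs the accompanying
    statistical battery: mixed-design ANOVA with Huynh-Feldt correction and
    generalized eta squared, simple-effects one-way ANOVAs, Tukey HSD, and
    independent t-tests. A pipeline driver reproduces the full
    simulate-measure-analyze workflow from a configuration and a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
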