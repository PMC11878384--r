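Package: fusefc
Title: Effective Functional Connectivity Analysis for Focused-Ultrasound
    Neuromodulation fMRI
Version: 0.1.0
Authors@R: person("fusefc", "maintainers", email = "fusefc@example.org",
    role = c("aut", "cre"))
Description: Psychophysiological-interaction (PPI) analysis of
    thalamocortical effective functional connectivity in block-design BOLD
    fMRI, with focused-ultrasound dose arithmetic (duty cycle,
    time-averaged power, cranial thermal index), a synthetic block-design
    BOLD generator with planted subnetwork structure and seed suppression,
    Chebyshev Type II temporal filtering, canonical and two-gamma
    haemodynamic response modelling, FDR plus cluster-extent activation
    detection, WPGMA hierarchical clustering with cophenetic statistics,
    and Dice/correlation-power network comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
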