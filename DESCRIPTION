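Package: adcue
Title: Kinetic-Occlusion Stimuli and Ideal-Observer Depth-Order Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes random-dot kinetic-occlusion (accretion-deletion)
    stimuli with exact control of surround flicker and region contrast, decides
    depth order from the accretion-deletion cue alone with a Bayes-optimal
    log-likelihood-ratio observer, estimates dense optic flow with the classic
    Horn-Schunck algorithm and detects the accretion-deletion zone, and
    simulates psychophysical depth-order reports together with the standard
    analyses (logistic psychometric fits, exact binomial proportions tests,
    chi-square residual-normality checks). A reproducible pipeline ties the
    stages together under a single master seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest,
    knitr,
    rmarkdown
Config/testthat/edition: 3
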