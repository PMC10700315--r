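Package: grazemeta
Title: Grazing Intensification, Dung Beetle Diversity and Dung Removal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired field experiments measuring how
    cattle-grazing intensification affects dung beetle communities and the
    dung removal they provide. Computes evaporation-corrected dung removal
    rates from wet/dry pat weights; community metrics including two
    functional dispersion indices (a standardized morphological trait space
    and a behaviour-constrained phenetic tree of guild-by-size functional
    groups); per-site Hedges' g effect sizes; random-effects meta-analysis
    and meta-regression with spatially correlated random effects fitted by
    REML and compared by AICc; principal-component summaries of climate and
    paired diversity differences; and piecewise structural equation models
    with d-separation basis sets and Fisher's C. A synthetic-data generator
    emulates the 38-landscape paired design with known ground truth so every
    stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
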