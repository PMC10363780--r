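Package: restsel
Title: Resting-Site Selection and Revisitation Analysis for Biologged Wild Boar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying the diurnal resting strategy of nocturnal,
    GPS- and accelerometer-collared animals (developed for wild boar, Sus
    scrofa). Segments 5-min activity series into one consolidated diurnal
    inactive phase per day, detects within-rest relocations from activity
    bouts plus GPS displacement, clusters daily resting locations into
    resting sites, derives landscape covariates (villages from building
    footprints by morphological closing, filtered road networks, dense
    vegetation), and fits use-availability resource-selection functions,
    selection ratios with Boyce-style k-fold cross-validation,
    zero-truncated Poisson revisitation models, and relocation-probability
    and relocation-distance mixed models. Includes a synthetic landscape and
    trajectory simulator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    MASS,
    glmmTMB,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
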