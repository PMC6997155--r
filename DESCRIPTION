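Package: cpforage
Title: Foraging Habitat Quality Analysis for Central-Place Foragers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links GPS telemetry of central-place foragers (e.g. colonial
    seabirds) to a prey species-distribution surface. Detects area-restricted
    search with first-passage time analysis, fits a maximum-entropy
    presence-background species distribution model with complementary log-log
    output, scores foraging locations against a colony-anchored resampling
    null model, and tests for differential seasonal improvement of occupied
    habitat quality with a beta-likelihood additive model and a pointwise
    difference-of-smooths procedure. Includes seeded synthetic generators for
    environments, prey presences, and two-mode forager tracks so the full
    pipeline is testable without field data.
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
    mgcv,
    nlme,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
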