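Package: logav
Title: Testing for Local Adaptation in Structured Metapopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests for local adaptation in structured metapopulations by
    comparing two estimates of the ancestral additive genetic variance: one
    obtained from between-population divergence and one from within-population
    resemblance, fitted jointly in a coancestry-aware mixed model (the LogAV
    test). Includes allele-sharing method-of-moments estimators of population
    coancestry and within-population relatedness, a blocked Gibbs sampler for
    the two-variance animal model, the classic Qst-Fst parametric-bootstrap
    test as a baseline, a forward-in-time Wright-Fisher metapopulation
    simulator with common-garden North Carolina II breeding designs, and a
    calibration harness for false-positive-rate and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
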