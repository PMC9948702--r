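Package: poolwell
Title: Pool-Well Cycling Simulations of a Four-Strain Cross-Feeding Community
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a synthetic four-strain Saccharomyces cerevisiae
    cross-feeding community (adenine, tryptophan, histidine and lysine
    overproducers) cycling between an unstructured pool phase, where strains
    grow exponentially in minimal medium, and a structured well phase, where
    96 compartments each receive a randomly sampled metabolite ecology and a
    randomly sampled inoculum and grow logistically under a shared carrying
    capacity. Growth in a well depends on whether each strain's three foreign
    metabolite requirements are met by the ecology or by cross-feeding
    partners; non-viable communities decay at a common death rate. Includes
    ecology distributions (uniform, Poisson-weighted, strain-driven metabolic
    feedback, keystone restrictions), scenario presets for timescale,
    carrying-capacity, niche-availability, feedback-timing and rescue
    experiments, replicate orchestration, and CSV/JSON result serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
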