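Package: pvasim
Title: Simulation Testing of Scalar and Matrix Population Viability
    Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for evaluating how model structure
    (count-based scalar versus age-structured Leslie matrix), process
    error, measurement error, and census time-series length jointly
    affect the precision and bias of projected ten-year percent
    population declines, the horizon used by IUCN Red List criterion
    A.3.  Age-structured "true" populations are simulated under
    beta-distributed vital-rate process error, corrupted with normal
    measurement error, and used to parameterize scalar and matrix
    population viability models whose resampled projections are compared
    against the true decline.  Ships the two study life histories: a
    ten-class hypothetical short-lived organism and the threatened snail
    Tasmaphena lamproides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
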