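Package: kelpcohorts
Title: Cohort Demography of Giant Kelp from Long-Term Quadrat Censuses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the demography of giant kelp (Macrocystis
    pyrifera) cohorts from long-term quarterly quadrat censuses and
    environmental series. Provides validated readers for census, plant and
    environment tables; bottom-temperature detrending and wave-energy
    covariate extraction; CLARA k-medoids clustering of quadrat algal
    assemblages into community states with gap-statistic selection of the
    number of clusters; rule-based detection of adult recruitment cohorts
    and their pulsed/trickled classification; Kaplan-Meier survivorship with
    right-censoring; factor analysis and penalized negative-binomial
    additive models of cohort size and longevity; and an individual-based
    simulator of disturbance-driven kelp forest dynamics with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    survival,
    mgcv,
    cluster,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
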