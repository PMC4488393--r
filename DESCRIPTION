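Package: clqas
Title: Design of Cluster Lot Quality Assurance Sampling Surveys
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing lot quality assurance sampling (LQAS)
    surveys under two-stage cluster sampling. Computes decision rules,
    minimal sample sizes, and misclassification risks under the
    binomial-scaled, beta-binomial, and quasi-binomial (effective sample
    size) cluster models as well as the simple-random-sampling baseline;
    converts between the sigma and rho clustering parameterizations;
    estimates between-cluster variance from published survey summary
    statistics; and evaluates candidate designs by exact probability
    calculations, seeded Monte Carlo simulation, and operating
    characteristic curves, including cost-minimizing searches over
    cluster geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
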