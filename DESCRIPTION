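Package: prevmod
Title: Complete Cancer Prevalence Estimation and Projection from Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and projects complete cancer prevalence from
    population-based registry data by combining age-period-cohort Poisson
    models of incidence, Pohar Perme net survival tabulation with mixture
    cure modelling, and a discrete transition-equation convolution of
    incidence, net survival and expected survival. Decomposes prevalence
    into phases of care (initial care, post-treatment monitoring, long-term
    survivorship, last year of life, and treatment for subsequent
    metastases or second primaries) to quantify survivor care needs, and
    validates the fitted system against observed cancer mortality. Includes
    a synthetic registry generator with known ground truth and a
    direct-counting microsimulation oracle for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
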