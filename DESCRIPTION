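Package: masafort
Title: Folic Acid Fortification Scenarios for Corn Masa Flour and
    Usual-Intake Exceedance of the Tolerable Upper Intake Level
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models folic acid fortification of corn masa flour on
    NHANES-style 24-hour dietary recall surveys and estimates the
    percentage of a population whose usual daily total folic acid intake
    exceeds the age-specific tolerable upper intake level (UL).  Provides
    a seeded synthetic survey generator with known ground truth, a
    fortification scenario engine driven by a corn-masa food-code list
    and a non-wholegrain gram proxy, 30-day supplement averaging, an
    analytic exclusion cascade, a measurement-error model that separates
    within-person from between-person variation in repeated recalls
    (power-family transformation, covariate adjustment, shrinkage), and
    delete-one-group jackknife replicate-weight variance estimation with
    paired scenario comparison tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
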