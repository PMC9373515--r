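Package: nrfbk
Title: Breakfast Diet Quality Scoring with the Nutrient-Rich Food Index (NRF9.3)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline from meal-coded 24-hour dietary recall records
    to breakfast diet-quality summaries: NRF9.3 nutrient-profiling scores with
    within-age-group tertiles, breakfast skipper classification by a 50 kcal
    energy rule, food-group consumer summaries, percentage contributions of
    breakfast to daily intake and to dietary recommendations with a 20
    percent benchmark, implausible-intake outlier substitution, a simplified
    within/between-person variance shrinkage estimator of usual intake, and
    survey-weighted descriptive estimates with trend and association tests.
    Includes a synthetic recall-data generator with known ground truth so the
    whole pipeline is testable without access to survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
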