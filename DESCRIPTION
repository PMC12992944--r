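Package: vtecs
Title: Risk Scoring and Evaluation of Thromboprophylaxis After Cesarean Section
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a department-style venous thromboembolism (VTE) risk
    scoring protocol for cesarean deliveries as a declarative, auditable rule
    set: itemized risk scores, postpartum hemorrhage markup, and tiered
    prophylaxis recommendations (early mobilization, pneumatic compression,
    low-molecular-weight heparin dosing). Ships comparator rule sets in the
    style of the RCOG, ACCP and ACOG guidelines, a seeded synthetic-cohort
    generator with independent Bernoulli risk factors and score-stratified
    event risks, an exact (weighted Poisson-binomial) score-distribution
    calculator, and the statistical evaluation pipeline: incidence estimates
    with exact Clopper-Pearson intervals, two-proportion chi-squared and
    Fisher tests, screening-test metrics, and number-needed-to-screen/treat.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
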