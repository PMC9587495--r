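Package: healthfacts
Title: Star-Schema Warehousing and Quality Audit of Routine Health Consultation Registers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Turns identity-free digital replicas of paper consultation registers into a
    star-schema fact table organised along a five-level health pyramid
    (country, region, district, facility, service). Free-text diagnoses, drug
    prescriptions and laboratory requests are mapped to ICD-10/ICPC-2, ATC and
    LOINC dictionary entries with a token Dice score; the materialised fact
    table supports ROLAP roll-up and drill-down over geography, time and
    medico-administrative dimensions. Data-quality audits cover field and
    reporting completeness, timeliness against a monthly deadline, and
    register-conformity accuracy, and paired user-evaluation matrices are
    scored and compared with an exact binomial McNemar test. A seeded
    synthetic-register generator provides fully controlled ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
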