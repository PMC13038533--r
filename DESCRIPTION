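Package: faersignal
Title: Disproportionality Signal Detection and Clinical Prioritization for
    Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FAERS-style
    spontaneous adverse event report tables. Reads the quarterly
    dollar-delimited DEMO/DRUG/REAC/OUTC/INDI files, removes duplicate
    reports by the regulatory variable-matching rule, restricts to suspect
    drugs and administration routes, and codes events at the MedDRA
    preferred-term level. Computes reporting odds ratios with Woolf
    confidence intervals and shrinkage-stabilized information components
    with closed-form credible bounds, flags statistically significant
    drug-event signals, and triages them with a five-dimension clinical
    priority rubric. Includes a synthetic report generator with planted
    relative reporting rates so every pipeline stage can be validated
    against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
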