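Package: lundgfr
Title: Dual-Marker Estimation of Glomerular Filtration Rate with an
    Internal Quality Check
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive estimation of glomerular filtration rate (GFR)
    from plasma cystatin C and creatinine using a pluggable registry of
    prediction equations, a concordance-based decision engine that
    arbitrates between the two markers using clinical flags (abnormal
    muscle mass, moderate-to-high-dose glucocorticoid therapy), refers
    discordant unexplained cases to invasive gold-standard measurement,
    and supports creatinine-anchored follow-up monitoring. Includes body
    surface area conversion between relative and absolute GFR, P30/P10
    accuracy metrics, and a seeded synthetic-cohort simulator with
    mechanistic confounders and multiplicative assay noise for validating
    the whole strategy against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
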