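Package: lynchrrs
Title: Gynecological Cancer Risk and Risk-Reducing Surgery Benefit in Lynch
    Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and gene-specific endometrial and ovarian cancer
    risks for women carrying pathogenic mismatch-repair variants (MLH1, MSH2,
    MSH6, PMS2) from prospective follow-up records. Person-years at risk and
    annual incidence rates are computed in 5-year age bins with censoring at
    organ removal, converted to cumulative and conditional age-interval risks
    by an annual recursion, and combined with Kaplan-Meier crude survival
    after cancer to quantify the cancers and deaths prevented by
    risk-reducing hysterectomy and/or bilateral salpingo-oophorectomy at
    chosen ages. A synthetic-cohort generator with known piecewise-constant
    hazards makes every stage testable without registry data and provides a
    closed-form risk oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
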