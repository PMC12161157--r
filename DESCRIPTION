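Package: fgmq
Title: Data Quality Assessment for Self- and Proxy-Reported Survey Data
    on Female Genital Mutilation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the quality of self-reported (women aged
    15-49) versus proxy-reported (daughters under 15, reported by their
    mothers) survey data on female genital mutilation (FGM) in
    DHS-style household surveys. Pools multiple surveys by
    denormalizing sample weights against population totals,
    redistributes approximate "during infancy" ages at FGM over the
    empirical distribution of precise early-childhood responses,
    profiles completeness of age-at-FGM reporting, computes a
    smooth-transition age-heaping index at ages 5, 10 and 15, fits a
    design-based logistic regression for reporting completeness
    (weighted IRLS with Taylor-linearized stratified-cluster sandwich
    variance), and estimates weighted median age at FGM by birth
    cohort. Includes a synthetic two-stage cluster-sample microdata
    generator with a known truth layer (heaping, infancy coding, item
    missingness) so every pipeline stage is testable without
    restricted-access survey data.
License: MIT
Encoding: UTF-8
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
RoxygenNote: 7.3.3
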