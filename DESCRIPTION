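Package: fopcap
Title: Front-of-Package 'High in' Labelling and Child-Appealing Packaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating packaged foods against Canada's mandatory
    front-of-package (FOP) 'high in' nutrition-symbol regulations, classifying
    child-appealing packaging (CAP) from coded marketing techniques, and
    comparing symbol prevalence between CAP and non-CAP products with exact
    contingency-table statistics. Includes a tiered percent-daily-value
    threshold engine (10/15/30 %DV with exemptions and main-dish rules), the
    proposed marketing-to-kids (M2K) nutrient criteria, stratified reporting
    tables, and a seeded synthetic food-supply generator emulating the
    structure of branded-food databases so the full pipeline is testable
    without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
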