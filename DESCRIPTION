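Package: vacomcat
Title: Bayesian Interpretation of Verbal Autopsies with Circumstances of
    Mortality Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interprets WHO-2016-shaped verbal autopsy (VA) records with an
    InterVA-style naive-Bayes engine driven by a user-supplied probability
    base ("probbase"). Each death receives, in parallel, a likelihood
    distribution over medical causes of death and over six Circumstances Of
    Mortality CATegories (COMCATs: traditions, emergencies, recognition,
    resources, health systems, inevitability), with a dominance rule that
    assigns a single COMCAT only when its likelihood exceeds 50% and a
    derived "multiple" category otherwise. Population-level summaries
    include cause-specific mortality fractions, COMCAT fractions, sex
    splits, person-year rates and internally age/sex standardised rates.
    A synthetic-data generator with known generating structure supports
    end-to-end testing and parameter-recovery experiments without access
    to confidential surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
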