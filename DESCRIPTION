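Package: o2commit
Title: Committed Ocean Deoxygenation in a Reduced Climate-Ocean Box Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An emission-driven, reduced-complexity global climate and ocean
    biogeochemistry box model for studying the zero-emission commitment of
    ocean deoxygenation, together with the diagnostics used to account for it:
    solubility-driven versus respiration- and residence-time-driven oxygen
    loss (via an abiotic oxygen twin tracer), an ideal-age ventilation tracer,
    oxygen-binned volume censuses with hypoxic and suboxic threshold volumes,
    region by depth-class oxygen budgets, the ocean heat to oxygen-loss ratio,
    and relative changes in the metabolic index of marine ectotherms. A seeded
    generator of gridded temperature and oxygen fields allows all diagnostics
    to be exercised without any simulator run. Inputs and outputs are tidy
    data frames; results carry tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
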