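Package: seabirdTEB
Title: Time-Energy Budget Modelling of Marine Bird Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the daily energy expenditure of marine birds (seabirds,
    sea ducks, divers and grebes) from time-activity budgets. Ships a collated
    table of activity-specific basal metabolic rate (BMR) multipliers for nine
    measured families together with an ecological-guild fallback for
    data-deficient families, allometric equations for BMR, lower critical
    temperature and medium-specific thermal conductance, and a
    thermoregulation-aware daily energy expenditure calculator that converts
    expenditure into required prey intake. Includes a year-round scenario
    simulator that reconstructs the energy budget of the extinct great auk
    (Pinguinus impennis) under three migration strategies using synthetic
    annual temperature cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
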