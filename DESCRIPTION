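Package: ibdtherapy
Title: Immune-Therapy Simulation for Inflammatory Bowel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a cytokine/T-helper-cell network model of the immune
    system in inflammatory bowel disease under three biologic therapies:
    anti-TNF-alpha and anti-IL-12 antibody neutralization, and recombinant
    IL-10 administration, delivered on an infliximab-style dosing schedule.
    Provides drug-free steady-state computation for healthy and patient
    parameterizations, four nominal patient-case scenarios classified by
    Th1/Th2 balance, a seeded generator of synthetic patient cases, and the
    evaluation statistics used to judge treatment quality: time-in-band
    occupancy of a healthy-individual interval and pro- to anti-inflammatory
    cytokine ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
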