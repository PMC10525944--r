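Package: qfclamp
Title: Action-Potential-Clamp Risk Stratification of HCN4 Loss-of-Function
    Sinus Bradycardia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in silico risk stratification of sinus bradycardia
    caused by loss-of-function mutations in the HCN4 pacemaker channel.
    Reconstructs the hyperpolarization-activated 'funny' current (If) under
    action-potential clamp with a human sinoatrial-node command waveform,
    integrates the inward charge carried by If during diastolic
    depolarization (Qf), simulates a single human sinoatrial-node pacemaker
    cell (Fabbri et al. 2017 <doi:10.1113/JP273259>) carrying each mutation
    under vagal, default and beta-adrenergic tone, and regresses Qf against
    model beating rates and against published clinical heart-rate data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
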