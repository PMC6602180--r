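Package: myelokin
Title: Transit-Compartment Models of Cytarabine-Induced Myelosuppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, personalisation and schedule analysis of white blood
    cell (WBC) dynamics during cytarabine (Ara-C) consolidation therapy for
    acute myeloid leukaemia. Implements a two-compartment Ara-C pharmacokinetic
    model with infusion-schedule handling, twelve Friberg-type
    transit-compartment myelosuppression model variants (M1-M12) with
    log-linear and secondary drug effects, per-cycle and per-patient parameter
    estimation by penalised nonlinear least squares, cross-validated
    prediction, Monte-Carlo parameter-uncertainty propagation, recovery-time
    based model discrimination across dosing schedules, treatment-timing
    simulation, and a synthetic-cohort generator emulating the statistical
    structure of clinical consolidation-cycle WBC data in NONMEM-dialect CSV.
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
    MASS,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
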