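Package: mhsd
Title: Regional Mental-Health System Dynamics: Simulation, Calibration and
    Multi-Objective Intervention Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stock-and-flow system dynamics model of psychological distress,
    mental-health service pathways and suicidal behaviour for a two-district
    health region. Provides a deterministic Euler simulator of an 11-stock
    service continuum (GP, psychiatrist/allied, community mental health,
    inpatient and online care) with capacity constraints, queueing and
    wait-time-driven disengagement; a catalogue of 12 suicide-prevention
    programs and service-capacity levers with scenario machinery; calibration
    of free model parameters to historical series by Powell's derivative-free
    method minimising summed mean absolute percent error; exhaustive
    enumeration of intervention combinations with Pareto (non-dominated)
    filtering across suicides, emergency-department presentations and service
    disengagement; Latin-hypercube sensitivity propagation; and a synthetic
    regional data generator so the full pipeline is testable without access
    to confidential regional datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
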