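Package: kpdsim
Title: Glucose-Insulin Dynamics and Remission Modelling for Ketosis-Prone Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a physiological model of ketosis-prone
    type 2 diabetes (KPD) in which fast glucose-insulin feedback is coupled
    to a reversible, glucose-driven inactivation of pancreatic beta cells
    and a slower permanent beta-cell death process. Provides stiff ODE
    simulation of clinical scenarios (high-sugar episodes, insulin courses,
    remission and relapse), fixed-point analysis of the reduced slow
    dynamics by companion-matrix polynomial root solving, bifurcation scans
    and phase diagrams over insulin sensitivity and beta-cell reserve, and
    closed-form optimal insulin-dosing schedules under a fasting-glucose
    floor. All results are returned as tidy tibbles with broom-style
    tidiers and ggplot2 autoplot methods.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
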