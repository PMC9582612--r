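Package: stimsafe
Title: Electrochemical Safety Limits for Electrophysiological Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and measuring the electrochemical safety
    limits of neural stimulation electrodes. Simulates the electrode-tissue
    interface as an equivalent circuit (constant-phase-element double layer,
    Faradaic branch, spreading and bulk tissue resistance) in 2-, 3- and
    4-contact configurations; delineates interface impedance from
    multi-configuration impedance spectra; detects the water electrolysis
    window from cyclic voltammetry; extracts cathodal excitation from
    voltage transients; fits a predictive log-model of interface
    polarization as a function of injected current, pulse width and
    reactance; inverts it to maximum safe injection currents; and compares
    the resulting limits with the empirical Shannon charge-density limit.
    Includes a seeded generator of benchtop-like and in-vivo-like synthetic
    measurement sets for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    deSolve,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
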