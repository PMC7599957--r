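Package: cholsim
Title: Kinetic Modelling of Hepatic Cholesterol Homeostasis and Ageing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic kinetic model of hepatic intracellular cholesterol
    homeostasis: a 30-reaction ODE network covering the mevalonate arm of
    cholesterol biosynthesis, free-cholesterol/cholesteryl-ester
    interconversion, LDL-cholesterol turnover with SREBP-2-regulated LDL
    receptor synthesis, and a reactive-oxygen-species/antioxidant subsystem.
    Provides stiff time-course integration, steady-state location with
    asymptotic-stability analysis, metabolic control analysis (flux and
    concentration control coefficients with summation-theorem checks),
    COPASI-style one- and two-dimensional parameter scans, ageing and
    acetyl-CoA scenario simulations, anchor-based parameter calibration,
    SBML Level 3 export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
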