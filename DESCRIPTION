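Package: mir31colitis
Title: Dynamic Modelling of MIR31-Balanced Inflammation and Epithelial
    Regeneration in DSS-Induced Colitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phenomenological Hill-kinetics ordinary differential equation
    model of the microRNA-31 (MIR31) regulatory network in dextran sulfate
    sodium (DSS) induced mouse colitis, covering NF-kB and STAT3 driven
    cytokine signalling, MIR31 induction, MIR31-mediated receptor repression
    and WNT/Hippo-driven epithelial regeneration.  Provides wild-type and
    MIR31-knockout simulation, a synthetic time-course data generator with
    replicate noise, bounded multi-start least-squares calibration,
    parameter-scaling sensitivity analysis of the proliferative-cell change
    ratio, and the MIR31 target-competition analysis (binding probabilities,
    action strengths, probability-curve intersections and DSS-concentration
    thresholds).  All results are returned as tibbles and compose with the
    tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
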