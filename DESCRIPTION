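Package: asunpbpk
Title: Whole-Body PBPK Modeling and Pediatric Dose Translation for the
    CD95L Inhibitor Asunercept
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic whole-body physiologically-based pharmacokinetic
    (PBPK) simulation of the Fc-fusion protein asunercept (APG101) in
    adults and children. Implements two-pore transcapillary transport of
    macromolecules, endosomal uptake with FcRn-mediated rescue from
    lysosomal degradation, reversible CD95L target binding, and a
    sialylation-dependent clearance pathway via the hepatic
    asialoglycoprotein receptor. Provides age- and sex-dependent virtual
    individuals and populations (1-100 years), non-compartmental analysis
    with geometric mean fold error model qualification, simultaneous
    multi-individual parameter estimation, synthetic Phase I/II study
    generation with cohort inclusion rules, and body-weight dose
    optimization that matches pediatric steady-state exposure to an adult
    reference population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    tools,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
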