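Package: fireCN
Title: Cyanide Exposure Reconstruction in Fire-Related Deaths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forensic analysis of hydrogen cyanide (HCN) inhalation in
    fire-related deaths. Provides a configurable multi-compartment
    physiologically based pharmacokinetic (PBPK) forward simulator of blood
    cyanide during constant HCN gas inhalation, an exhaustive grid-search
    inverse estimator of inhaled concentration and inhalation time from
    paired left/right cardiac blood measurements, exposure-group
    classification with measurement-uncertainty sensitivity analysis,
    censoring-aware cohort statistics (detection summary, carboxyhemoglobin
    and cyanide poisoning zones, thiocyanate group comparison), and a
    synthetic-cohort generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
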