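Package: respdose
Title: Respiratory Aerosol Deposition and Airway Obstruction Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-lung dosimetry of inhaled lognormally distributed inert dust
    aerosols in rat-like and human airway trees under acute exposure scenarios.
    Implements lognormal aerosol discretization, Cunningham slip correction,
    settling and diffusion transport coefficients, species-specific inhalability,
    empirical extrathoracic (head) filtration, and a serial-filtration
    multiple-path deposition engine over tidal breathing with a finite tidal-front
    penetration model. From per-airway deposited masses it computes the airway
    obstruction statistic: the ratio of the diameter of the coalesced deposited
    aerosol mass per airway to that airway's diameter, with binned distributions
    and cross-species, cross-concentration comparison. Ships the symmetric
    24-generation typical-path human airway geometry and a reproducible generator
    for synthetic monopodial rat-like airway trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
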