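Package: scsolub
Title: Solubility of Solid Solutes in Supercritical Carbon Dioxide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement reduction, correlation and thermodynamic modelling of
    solid-solute solubility in supercritical carbon dioxide. Converts
    trapped-sample measurements to equilibrium mole fractions, correlates
    isothermal solubility data with ten density-based semi-empirical models
    (Chrastil, Mendez-Santiago-Teja, Kumar-Johnston, Bartle, Bian, Garlapati,
    Keshmiri, Khansary, Sodeifian, Belghait) by AARD minimisation, extracts
    dissolution and vaporization enthalpies, runs linear-collapse
    self-consistency tests, and solves solid-fluid equilibrium with the
    Peng-Robinson equation of state under van der Waals, Wong-Sandler and
    Huron-Vidal mixing rules with a pluggable excess-Gibbs model. Ships the
    palbociclib study dataset and a synthetic-data generator emulating its
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
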