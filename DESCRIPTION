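Package: oxylume
Title: Chemiluminescence-Based Quantification of Extracellular Superoxide
Version: 0.1.0
Authors@R:
    person("Ben", "Halloran", email = "bhalloran@example.org", role = c("aut", "cre"))
Description: Tools for quantifying extracellular superoxide from flow-injection
    chemiluminescence (MCLA/FeLume-type) measurements at coral surfaces and in
    culture. Provides a kinetic simulator for synthetic traces (piecewise-constant
    production, pseudo-first-order decay, transit-delay attenuation, SOD quench
    events), plateau detection by a coefficient-of-variation rule, tiered blank
    correction, KO2 primary-standard quantification from A240 absorbance,
    log-linear decay fitting with backward extrapolation, calibration curves with
    3-sigma detection limits and matrix half-lives, steady-state concentration
    and per-organism net production rates, and the associated group and
    community statistics (Type-II two-way ANOVA, Tukey-Kramer HSD, two-sample
    t-tests, Bray-Curtis dissimilarity and ANOSIM with permutation p-values).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
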