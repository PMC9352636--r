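Package: bapbk
Title: Physiologically Based Kinetic Modelling of Bile-Acid Homeostasis and
    BSEP Inhibition
Version: 0.1.0
Authors@R:
    person("bapbk", "developers", email = "bapbk@example.org", role = c("aut", "cre"))
Description: Coupled physiologically based kinetic (PBK) models of
    glycochenodeoxycholic acid (GCDCA) homeostasis, the dual endothelin-receptor
    antagonist bosentan and its active metabolite RO 47-8634, with
    non-competitive inhibition of the bile salt export pump (BSEP) linking the
    drug models to the bile-acid model. Includes enterohepatic circulation with
    discrete gall-bladder emptying events, in vitro-to-in vivo extrapolation of
    BSEP transport capacity from transporter abundance, normalized local
    sensitivity analysis, Monte Carlo virtual populations over BSEP abundance,
    empirical bile-acid-pool scaling scenarios, a synthetic postprandial /
    drug-PK data generator, and least-squares calibration of absorption and
    biliary-excretion constants. Ships its own adaptive Dormand-Prince ODE
    integrator (compiled and pure-R reference implementations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
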