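Package: ptgsim
Title: Multi-Timescale Simulation of Parathyroid Gland Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic simulator of parathyroid gland (PTG) physiology
    driven by prescribed time courses of ionized calcium, phosphate, and
    1,25-dihydroxyvitamin D. Couples calcium-sensing receptor (CaSR) and
    vitamin D receptor (VDR) expression dynamics, three parallel CaSR
    signaling pathways controlling intracellular parathyroid hormone (PTH)
    degradation, PTH production, and cell proliferation, a stored/serum PTH
    pool model with a steep sigmoidal release set-point, and a two-compartment
    gland growth model with a dynamic, irreversible carrying capacity. The
    coupled 21-state stiff system spans seconds to years and is integrated
    with an adaptive embedded Runge-Kutta method with exact restarts at input
    breakpoints. Includes scenario builders for acute hypocalcemia, secretion
    hysteresis, chronic hypocalcemia, and chronic kidney disease protocols, a
    one-at-a-time parameter sensitivity sweep, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
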