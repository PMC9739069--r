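Package: lulcsim
Title: Logistic-CA-Markov Land-Use Simulation with Biocapacity and
    Landscape-Pattern Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating land-use/land-cover (LULC) change on
    categorical rasters with a Logistic-CA-Markov model: per-class logistic
    suitability atlases fitted on driver stacks, Markov transition-matrix
    estimation and area projection, cellular-automaton spatial allocation
    under hard Markov quotas, Kappa map validation, biocapacity accounting
    from yield and equivalence factors, and a FRAGSTATS-style landscape
    metric suite (NP, MPS, LPI, PSCV, DIVISION, AI, SHDI). Includes a
    seeded synthetic-scenario generator (drivers, initial map, forward
    transitions with known coefficients and transition matrix) so every
    stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
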