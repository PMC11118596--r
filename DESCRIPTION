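Package: spvtissue
Title: Self-Propelled Voronoi Tissues with Mechanically Regulated Growth and Cell Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates confluent cell monolayers as a self-propelled Voronoi
    (SPV) model on a periodic square box, with an area-and-perimeter elastic
    energy, analytic forces on the cell centers, overdamped active dynamics,
    and a stochastic birth-death process whose rates are coupled to cell
    mechanics (realized area or hydrostatic pressure). Provides machinery for
    mutant-invasion experiments between two cell types, selection-coefficient
    estimation from logistic fraction dynamics, a non-growing-mixture fitness
    predictor, and closed-form mean-field fitness formulas, together with
    lattice and random-tissue fixtures, YAML run configuration, CSV/JSON
    writers and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
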