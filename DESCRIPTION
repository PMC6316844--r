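Package: nucleosorb
Title: Adsorption Analysis of Nucleotides on Phyllosilicate Minerals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and modelling of nucleotide adsorption on clay
    (phyllosilicate) mineral surfaces. Converts batch-adsorption measurements
    into quality-checked isotherms via Beer-Lambert calibration and mass
    balance; normalizes isotherms to solute solubility and to basal, lateral
    (edge), or total specific surface area and scores the collapse of
    homologous-molecule families; fits classic and modified (solid/liquid,
    dimensionless-constant) Langmuir models with standard free energies;
    decomposes low-pressure quasi-equilibrium argon adsorption derivative
    isotherms into local adsorption domains (Derivative Isotherm Summation)
    to estimate edge versus basal surface proportions; and post-processes
    molecular-dynamics trajectories of a nucleotide near a clay slab into
    adsorption states, residence statistics, and complexed-molecule charges.
    Includes seeded synthetic-data generators with known ground truth for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
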