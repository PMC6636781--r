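Package: phagetrans
Title: Individual-Based Simulation of Generalized Transduction and Lysogeny
    in Phage-Bacteria Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic, individual-based model of bacteria and
    bacteriophage on a two-dimensional lattice, with explicit gene-level
    genomes, temperate and virulent phage lifestyles, headful packaging of
    host DNA into defective transducing particles (generalized
    transduction), superinfection immunity of lysogens, stress-dependent
    sigmoidal prophage induction, antibiotic selection, and
    fitness-proportional (roulette-wheel) reproduction into free lattice
    sites. Ships the in-silico experiments built on the model: a two-phase
    infection protocol comparing four phage types (temperate/virulent x
    transducing/non-transducing), a two-lysogen resistance-gene shuffling
    experiment with dual antibiotic exposure, random-forest
    permutation-importance sensitivity analysis of phage survival, parameter
    sweep heatmaps, and lysate DNA-capacity arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
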