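Package: fangmark
Title: Snakebite Mark Classification with Edge-Node Planning and Feedback Retraining
Version: 0.1.0
Authors@R:
    person("Fangmark", "Developers", email = "fangmark@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for identifying venomous (cobra) snakebite marks from
    skin images: a seeded two-class synthetic bite-mark image generator, exposure-fusion
    contrast enhancement, rotation/zoom augmentation, a small convolutional neural network
    classifier implemented in base R with a seeded training harness, confusion-matrix
    evaluation (sensitivity, specificity, accuracy, AUC), a profit objective for choosing
    the number of edge compute nodes per state maximised by particle swarm optimisation
    (PSO), quantum-behaved PSO (QPSO) or exhaustive search, and a simulator of the
    cloud-edge feedback loop in which misclassified cases are returned to the cloud for
    retraining.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
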