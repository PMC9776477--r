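Package: histosdl
Title: Synergic Deep Learning for Histopathology Image Classification with
    Bald Eagle Search Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a histopathology
    image classification pipeline: median-filter preprocessing, a synergic
    deep learning (SDL) ensemble of small convolutional networks supervised
    jointly through pairwise synergic networks, hyperparameter tuning by an
    improved bald eagle search optimizer (bald eagle search plus
    oppositional-based learning), and an LSTM classification head over the
    ensemble's feature vectors.  Ships a seeded synthetic image generator
    emulating a class-imbalanced histopathology dataset, a multiclass
    metrics engine (accuracy, precision, recall, specificity, F-score,
    G-mean, per class and macro), and end-to-end pipeline orchestration,
    so every stage runs and is tested without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
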