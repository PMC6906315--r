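Package: enscode
Title: Inverted Encoding Models for Ensemble Orientation Coding in EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decoding pipeline for visual working memory of orientation
    ensembles from epoched multichannel EEG. Implements an inverted
    encoding model (IEM) with a cosine-power channel basis, three-fold
    cross-validated channel tuning function (CTF) reconstruction and its
    slope statistic, temporal generalization matrices, a stable/dynamic
    coding index built from per-cell significance maps, cross-condition
    generalization from single-orientation to ensemble displays,
    label-shuffling permutation inference and participant-level
    bootstrapping, psychometric old/new modelling with a cumulative
    Weibull maximum-likelihood fit, continuous-estimation bias and
    circular-median-split analyses, and a forward-model synthetic data
    generator so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
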