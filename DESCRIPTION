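Package: tvigan
Title: In-Silico to In-Vivo Domain Translation of Muscle Tissue Velocity Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling intra-muscular contraction dynamics with unpaired
    domain translation. Provides a motor-unit twitch-superposition simulator of
    tissue-velocity image (TVI) sequences, the experimental preprocessing chain
    (Butterworth bandpass, spatial median filtering, bicubic resampling,
    standardization), a synthetic surrogate for in-vivo sequences, a modified
    3D (2D+time) cycleGAN translator with temporal-stride control and stochastic
    noise injection, and a spatio-temporal feature-evaluation toolkit (variance
    maps, histogram correlation, Bhattacharyya distance, K-space structural
    similarity, power-spectral-density correlation, content cross-correlation)
    together with generator similarity maps and depth profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
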