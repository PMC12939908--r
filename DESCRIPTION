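Package: mefc
Title: Multi-Entropy Feature Concatenation for Single-Channel EEG Dementia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a similarity-based, template-matching pipeline for
    classifying Alzheimer's disease, frontotemporal dementia, and healthy
    controls from single-channel resting-state EEG. A four-level Daubechies-4
    discrete wavelet transform separates the five classical brain rhythms
    (delta, theta, alpha, beta, gamma); permutation entropy, sample entropy,
    and singular-spectrum entropy are computed per rhythm and concatenated
    into a multi-entropy feature vector; unknown samples are classified by
    their similarity (dynamic time warping, Pearson correlation, wavelet
    coherence, or Hilbert envelope correlation) to per-class mean templates
    under leave-one-out cross-validation. Includes EDF/CSV readers, a
    rational polyphase resampler, a seeded class-conditional synthetic EEG
    cohort generator, and a channel-by-rhythm-by-measure evaluation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
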