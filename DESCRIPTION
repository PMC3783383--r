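Package: cricketsong
Title: Species Identification from Field-Cricket Calling Songs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for acoustic species identification in field crickets
    (Gryllinae). Synthesizes calling songs with known temporal structure,
    segments syllables and chirps from waveforms, and computes the five
    standard song features (call period, call duration, syllable period,
    syllable duration, dominant frequency) plus two chirp-superstructure
    statistics (constancy factor and relative variance). Classifies
    individuals to species by discriminant function analysis with a pooled
    within-group covariance and by single-linkage clustering with a
    normalized linkage cutoff, and drives a randomized evaluation of both
    methods across taxa subsets and character sets with binomial GLM
    inference, arcsine bootstrap confidence intervals and two-proportion
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'classify.R'
    'cricketsong-package.R'
    'experiments.R'
    'features.R'
    'fixtures.R'
    'methods.R'
    'preprocess.R'
    'synth.R'
    'wav.R'
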