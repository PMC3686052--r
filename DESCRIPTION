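Package: mirrorloop
Title: Eligibility-Weighted Hebbian Learning of Sensorimotor Inverse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator for the formation of mirror neurons and control-theoretic
    inverse models in a closed sensorimotor loop. Sensory-to-motor synaptic
    weights are learned during motor exploration by a Hebbian rule in which
    potentiation is windowed by a postsynaptic eligibility trace and stabilized
    by equal-time heterosynaptic depression. Provides generators for variable
    (uncorrelated) and stereotyped (traveling-pulse) motor rate codes, a delayed
    linear motor-to-sensory feedback map, closed-form steady-state predictions
    (causal and predictive inverses), in-silico mirroring experiments that
    measure mirroring offsets and peak cross-correlation ratios, feedforward
    imitation demos, and an exactly enumerable binary model of mirroring
    strength under intrinsic noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, MathematicalBiology, NeuroScience
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'motor-codes.R'
    'feedback-loop.R'
    'eligibility.R'
    'hebbian-learning.R'
    'mirroring.R'
    'imitation.R'
    'binary-mirror.R'
    'io.R'
    'experiment.R'
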