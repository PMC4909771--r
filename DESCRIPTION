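Package: synaptica
Title: Structural Plasticity, Effectual Connectivity, and Associative Memory Capacity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of binary associative memory (Willshaw and zip networks)
    under structural synaptic plasticity. Provides generators for sparse
    random pattern sets and potential-synapse graphs; anatomical, potential,
    effectual and target connectivity measures; stochastic per-synapse and
    deterministic macroscopic simulators of consolidation dynamics with
    homeostatic synaptogenesis; exact finite-size and Gaussian
    signal-to-noise storage-capacity analyses at cortical macrocolumn
    parameters; transfer-entropy bounds relating storage capacity to
    functional connectivity; and the closed-form spacing-effect theory for
    optimal rehearsal gaps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
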