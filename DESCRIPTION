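Package: refgame
Title: Reference Games Between Neural Agents with Controlled Perceptual Biases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A simulation and analysis framework for studying the mutual
    influence between visual representation learning and emergent communication.
    Sender and receiver agents, each composed of a convolutional vision module
    and a recurrent (GRU) language module, play a Lewis-style reference game
    over synthetic multi-attribute object images. Perceptual biases are induced
    by relational label smoothing during classifier pretraining; communication
    is trained with REINFORCE; biases are quantified with representational
    similarity analysis (RSA) and information-theoretic effectiveness scores;
    and the evolutionary stability of bias types is analysed on symmetrized
    payoff matrices. All neural components (convolution, GRU, policy gradients)
    are implemented in base R with finite-difference-verified gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    png,
    hdf5r
Config/testthat/edition: 3
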