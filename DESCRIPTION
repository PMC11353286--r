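Package: affsyn
Title: Synergistic Information and Capacity-Limited Encoding in Multimodal Affordance Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the perception of multimodal affordances as lossy
    communication over two capacity-limited sensory channels. An affordance
    landscape is a real-valued matrix whose two axes are ambient energy
    arrays; each axis is observed by a deterministic encoder restricted to L
    signals and a downstream conditional-expectation decoder reconstructs
    the affordance value. The package provides discrete information measures
    (entropy, mutual information, distance-weighted spatial entropy),
    partial information decomposition with BROJA-style union information and
    synergy (including WholeMinusSum and Smax bounds and a brute-force
    oracle), direct and indirect encoding objectives optimized by stochastic
    hill climbing with an exhaustive-search certificate, synthetic landscape
    generators (a worked 4x4 fixture, XOR gates, block-synergistic and
    quantized blob-image landscapes), and batch experiments comparing the
    two encoding strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
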