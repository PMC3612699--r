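Package: ReVis
Title: Recurrent Rate-Code Network Simulator for Occluded Object
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a hierarchical recurrent rate-code neural network of
    the ventral visual pathway (V1, V2/V4, IT, output and optional semantic
    layers) with k-winners-take-all inhibitory competition, bidirectional
    excitatory projections and two-phase contrastive error-driven learning.
    Includes a Gabor filter-bank front-end, Gaussian-edged blob occlusion of
    images, a synthetic shape dataset generator, sparse binary semantic
    pattern shaping toward a target similarity matrix, feedforward
    backpropagation comparison networks, and analysis tools for completion
    trajectories, majority-vote recognition accuracy, occlusion sweeps and
    representational similarity (distance-matrix) comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'analysis.R'
    'experiment.R'
    'imageprep.R'
    'utils.R'
    'v1.R'
    'netcore.R'
    'learning.R'
    'occlusion.R'
    'semantics.R'
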