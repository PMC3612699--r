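# ReVis

Recurrent rate-code network simulator for occluded object recognition.

## What this is

How does a visual system that recognizes objects through a feedforward
hierarchy (V1 → V2/V4 → IT → category output) benefit from the massive
*recurrent* connectivity of cortex? ReVis implements a desk-scale simulator
and analysis toolkit for studying that question: a layered rate-code
network with

- **k-winners-take-all (kWTA) inhibition** within every layer — a shared
  inhibitory conductance g_i placed between the k-th and (k+1)-th unit's
  threshold conductance, so at most k of n units stay above threshold and
  codes are sparse;
- **bidirectional excitatory projections** — every feedforward projection
  between hidden layers has a feedback twin (transmission scaled by
  `fbScale`), and a *feedback lesion* silences top-down flow exactly while
  leaving weights intact;
- **conductance-based point neurons** — per cycle,
  `V_m ← V_m + dt·[g_e(E_e−V_m) + g_i(E_i−V_m) + g_l(E_l−V_m)]`, with
  activation a logistic function of `V_m − θ`;
- **two-phase error-driven learning** — contrastive Hebbian updates
  `Δw = ε[(1−m)(x⁺y⁺ − x⁻y⁻) + m·y⁺(x⁺ − w)]` over a minus phase (image
  clamped) and a plus phase (image + category target + optional semantic
  pattern clamped), with soft weight bounding;
- **blob occlusion** — images degraded toward background gray by
  Gaussian-edged circular masks (plateau radius and σ both 5% of image
  size; occlusion level `O` maps to `N = ⌊2.5·O·(I/H + 1) + 0.5⌋`
  applications), avoiding novel edge artifacts;
- **semantic pattern shaping** — sparse binary category vectors (25%
  active) ratcheted toward a target similarity matrix by accepted-only
  on/off bit-pair flips;
- **measurement machinery** — per-cycle completion trajectories (cosine to
  the unoccluded settled state per layer), 7-transform majority voting with
  a second-order vote across renders, occlusion sweeps across model
  variants, and representational-similarity (distance-matrix) comparisons.

Feedforward backpropagation comparison networks (a sparse and a
distributed parameterization) share the layer structure and front end.
A synthetic shape-dataset generator emulates the category / exemplar /
render structure of a rendered 3-D object corpus so everything runs
without downloads.

## Worked example

```r
library(ReVis)

# a 5-category synthetic dataset: 3 exemplars x 2 renders, 24 px images
ds   <- makeSyntheticDataset(syntheticDatasetSpec(5, 3, 2, imageSize = 24, seed = 42))
bank <- buildFilterBank(poolSize = 4)
spec <- kwtaNetworkSpec(bank, 24, ds$categories, v2Size = 120, itSize = 80)
net  <- buildNetwork(spec, seed = 1)

tr <- trainNetwork(net, ds, ds$manifest,
                   trainProtocol(epochs = 30, lrate = 0.05, seed = 2,
                                 voteEvery = 5, stopAccuracy = 95),
                   images = lapply(seq_len(nrow(ds$manifest)),
                                   function(i) renderImage(ds, i)))
tail(tr$log, 1)
#>    epoch trainAcc meanCycles  voteAcc
#> 10    10 66.66667       56.6 96.66667

evaluateAccuracy(tr$net, ds, ds$manifest, voteMode = "vote2d", seed = 5)
#> [1] 90
```

`trainAcc` is the percentage of training presentations whose minus-phase
(free-running) output winner was the true category during that epoch under
the random affine augmentation; `voteAcc` is 7-transform voted accuracy at
the voting cadence (training stops once it reaches `stopAccuracy` and the
best-voted snapshot is returned); `meanCycles` is the mean settling length.
The final call rescores 7-transform majority voting with fresh transforms.
Under 50% blob occlusion the same evaluation degrades gracefully:

```r
evaluateAccuracy(tr$net, ds, ds$manifest, voteMode = "vote2d", O = 0.5, seed = 5)
#> [1] 66.66667
```

Completion under occlusion (cosine of each layer's state to its unoccluded
reference): the object representation at the top of the hierarchy is
restored almost perfectly while the input layer stays incomplete:

```r
img <- renderImage(ds, 1)
traj <- completionTrajectory(tr$net, img, O = 0.5, occlusionSeed = 11)
sapply(split(traj, traj$layer), function(d) tail(d$cosine, 1))
#>        IT    Output        V1        V2
#> 0.9997201 0.9999872 0.9623065 0.9926663
```

Whole experiments (baseline / occlusion sweep / semantics / completion)
run from a single config with `runExperiment()`; see
`inst/scripts/run_experiment.R` for the shell entry point and
`vignettes/recurrent-vision-methods.Rmd` for the model, parameters and
design decisions.

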