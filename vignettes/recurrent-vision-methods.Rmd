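---
title: "ReVis: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ReVis: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ReVis simulates a hierarchical, recurrently connected rate-code network of
the ventral visual pathway and the measurement machinery used to study it:
recognition of object categories from grayscale images, robustness to
Gaussian-edged blob occlusion, per-cycle "completion" trajectories, and the
shaping of high-level visual representations by semantic structure. This
vignette explains the model, its assumptions, the tunable parameters, and
the design decisions taken where more than one reasonable choice existed.

## The model

### Front end

Images are normalized to square grayscale matrices in [0,1] (the reference
working size is 144 px; the desk-scale examples in the tests use 24 px) and
encoded by a fixed V1-like filter bank: even/odd Gabor quadrature pairs
(simple cells) at 4 orientations and 2 dyadic scales, rectified, max-pooled
over phase and a small spatial neighborhood (complex cells), normalized by
each filter's fixed response to a full-contrast preferred edge, and
sparsified by k-winners-take-all (kWTA) so at most a configured fraction
(default 15--25%) of units is active. The exact filter parameters of the
original model are not public; the bank here is a declared surrogate with
every parameter configurable (`buildFilterBank`), not a reconstruction.

The complex-cell pooling neighborhood (`poolSize`) sets the front end's
tolerance to small translations. At the 24-px working size used throughout
the tests, training presentations are augmented with translations of up to
15% of the image (about 3.6 px), so the default pooling of 4 px was chosen
to put single-cell receptive-field shifts on the same scale as the
augmentation jitter; with 2-px pooling the same network is essentially
unable to learn under augmentation at this image size, because every
presentation produces an almost disjoint V1 code.

### Recurrent network

Layers V1 (input) -> V2 (standing in for V2/V4) -> IT -> Output, plus an
optional Semantics layer bidirectionally linked to IT. All adjacent layers
above V1 are reciprocally connected. Each unit is a conductance-based point
neuron in normalized units:

    V_m <- V_m + dt * [ g_e (E_e - V_m) + g_i (E_i - V_m) + g_l (E_l - V_m) ]

with reversal potentials E_e = 1.0 > theta = 0.5 > E_l = 0.3 > E_i = 0.15,
leak g_l = 0.1, dt = 0.3, and activation a logistic function of
(V_m - theta) with gain 300. Excitatory conductance is the weighted sum of
sender activations, normalized by the sender layer's expected active count
(its k), times an absolute feedforward scale of 2; feedback projections
transmit at 0.2 of feedforward strength (`fbScale`), and the feedback
lesion multiplies their transmission by exactly zero without touching
weights.

Why these numbers:

* **Normalization by expected active count** rather than raw sender count:
  with ~15% sparse senders, dividing by the full sender count leaves
  excitatory drives an order of magnitude below the inhibition-implied
  threshold, so no unit can ever win. Dividing by the expected number of
  active senders puts typical drives near 0.5 regardless of layer size.
* **ffScale = 2** sets the total conductance, and with it the membrane time
  constant, to a few cycles, so settling completes in tens of cycles
  (20--50 on the test fixtures) rather than creeping below the convergence
  tolerance while far from equilibrium.
* **gain = 300**: the kWTA inhibition compresses the membrane-potential
  spread within a layer to a few thousandths of a normalized unit; a
  shallow activation function turns that spread into near-uniform
  activations (every cosine between states is then ~1), while an overly
  steep one makes activations effectively binary and settling oscillatory.
  300 leaves winners graded but well separated from losers.
* **Weight initialization** is uniform 0.5 +/- 0.25, with each receiving
  unit's incoming mean equalized to 0.5 exactly. Without the equalization,
  a unit's random mean weight dominates its drive when a hundred-odd
  senders are active, so the same units win for *every* input and
  representations carry no stimulus information; equalizing the means makes
  initial winners reflect input-pattern overlap, which learning then
  sharpens.

### Inhibition

Within each layer a single shared inhibitory conductance implements kWTA:
for each unit one computes the inhibition g_Theta that would hold it
exactly at threshold given its excitatory drive, and the layer inhibition
is placed between the k-th and (k+1)-th largest values,
g_i = g_Theta(k+1) + q (g_Theta(k) - g_Theta(k+1)), q = 0.25. That bounds
the number of above-threshold units at *equilibrium*, but not during the
transient while membrane potentials integrate: a unit whose equilibrium is
below threshold can still be above it for a few cycles after the drive
shifts. Because the stepped membrane potential is linear in g_i, the
minimal extra inhibition that keeps at most k units above threshold after
the current step has a closed form, and the implementation takes the
maximum of the two values each cycle ("fast within-cycle inhibition",
reflecting the faster dynamics of inhibitory interneurons). The activity
bound then holds at every cycle, which the tests assert. Ties are broken
by stable unit order; a layer of exactly equal drives resolves all-or-none.

### Learning

Two-phase contrastive (error-driven) learning: a minus phase settles with
the image clamped on V1 and everything else free; a plus phase continues
from that state with the one-hot category output (and, when the semantics
experiment is enabled, the category's semantic pattern) also clamped. Every
projection, feedback included, then updates by

    dW = lrate * [ (1 - m) (x+ y+ - x- y-) + m y+ (x+ - W) ]

with Hebbian mix m = 0.01, and soft weight bounding (increases scaled by
1 - w, decreases by w) that keeps weights in [0,1] under any update
sequence. The default learning rate is 0.1: 0.3 destabilizes training on
the test fixtures, 0.01 is needlessly slow. The exact learning rule of the
original implementation is in an unavailable supplement; contrastive
Hebbian learning over the two phases is the canonical published composition
for this model family and is used here with all coefficients exposed.

Training supports a voting cadence (`voteEvery`): every few epochs the
network is scored by 7-transform majority voting on the training manifest,
training stops once that reaches `stopAccuracy`, and the best-voted
snapshot is returned. Within-epoch minus-phase accuracy is a noisy,
pessimistic signal under augmentation (and contrastive learning on small
layers can degrade late in training), so voted-accuracy early stopping is
the recommended protocol and is what the packaged test fixtures use.

The backpropagation comparison networks share the layer sizes but are
purely feedforward logistic-unit networks trained by backpropagation of
cross-entropy error with an error tolerance of 0.05 (units within
tolerance of their target contribute zero gradient; the loss value itself
is not gated -- the gating is about what drives learning). The printed
equation for the cross-entropy omits its leading minus sign; it is
implemented as the conventional non-negative loss. The "sparse" variant
uses bias weights of -3.0, learning rate 0.2 and kWTA-filtered V1 input;
the "distrib" variant uses zero biases, learning rate 0.01 and the dense
(non-kWTA) V1 responses. Plain SGD, no momentum, no weight decay.

## Occlusion

The blob occluder is weight 1.0 inside a circle of radius 5% of the image
size (floored: 7 px at 144), Gaussian falloff with sigma also 5%
(floored), on a square support of side 2 (r + 2 sigma) = 42 px at 144. The
occlusion level O in [0,1] maps to an application count
N = floor(2.5 O (I/H + 1) + 0.5) -- the floor-plus-half makes the
continuous rule a round-half-up integer with N(0) = 0. Each application is
pasted at an integer position drawn uniformly over the image square
(partial off-image blobs allowed, fresh position per application), and
overlapping placements combine by per-pixel maximum of weights, so plateau
regions are always *exactly* the background gray; the multiplicative
alternative was rejected because overlapping skirts would darken below the
background. The occluded image is w * background + (1 - w) * image. The
rounding convention that produced the printed 7-px and 42-px figures is
not stated in the source; flooring reproduces both. Occlusion masks are
applied before the voting transforms so occluded features are identical
across a trial's presentations.

## Semantic patterns

Category-level semantic structure enters as sparse binary patterns (25% of
units active) shaped toward a target similarity matrix. Real corpus-derived
similarities are not fetched; targets are synthetic block matrices
(within-cluster similarity > between-cluster, optional superordinate
blocks, `makeTargetDM`) or any user-supplied CSV matrix. Shaping is a
ratchet: propose one on/off bit pair per iteration (softmax-weighted by the
summed target-similarity-times-other-patterns'-bits score for the on bit,
and the complementary weighting for the off bit; temperature 1.0), keep
the flip only if the mean absolute off-diagonal difference between the
patterns' cosine matrix and the target strictly decreases. Activity is
conserved exactly by construction, and the fit trace is strictly monotone.
The source description of the proposal weighting is ambiguous about
normalization; the per-bit score is used as stated, unnormalized, inside
the softmax.

## Measurement machinery

* **Completion trajectories**: per cycle and layer, the cosine of the
  activation to that layer's settled state for the *unoccluded* image under
  the same affine transform (sharing the transform isolates occlusion's
  effect). At zero occlusion every layer's trajectory ends at 1 by
  construction.
* **Voting**: seven presentations with fresh affine transforms, modal
  winner, ties broken by summed output activation then lowest category
  index (deterministic). A second-order vote takes the modal first-order
  winner across an exemplar's renders.
* **RSA comparisons**: category mean activations at a layer, pairwise
  cosines, and Pearson correlation over off-diagonal upper-triangle
  entries between matrices.
* **Semantic inference**: settle with V1 clamped and the semantics layer
  free; report per-cycle cosines of the semantics activation to every
  category's canonical pattern and the final ranking.

## Synthetic dataset generator

The generator emulates the category / exemplar / render structure of a
rendered 3-D object corpus. Each category draws a base shape of 2--4
soft-edged parametric primitives (disks, rings, bars, wedges) with its own
seeded geometry; exemplars jitter that geometry (positions, sizes,
orientations, gray values; default magnitude 0.12); renders apply a
smaller pose jitter and a multiplicative brightness gradient from a random
overhead angle (default 0.05), statistically emulating modest in-depth
rotation and overhead-arc lighting variability. Exemplar variation exceeds
render variation by construction, which the tests assert. Everything is
derived deterministically from the spec seed, and manifests are cheap
because images render lazily.

What the generator does *not* emulate: real 3-D occlusion and
self-occlusion geometry, articulated or textured objects, background
clutter, and the long-tailed difficulty distribution of photographed
categories. Passing the scaled tests therefore demonstrates that the
mechanisms behave as described on controlled synthetic imagery, not that
the full-scale accuracies of the original study would be reproduced.

## Scaled test conditions

The test suite runs everything at desk scale, chosen once as the smallest
sizes at which the studied effects are measurable: 24-px images, the
4-orientation / 2-scale bank with 4-px pooling, hidden layers of ~100/60
units, 4--10 categories with 2--3 exemplars and 1--2 renders, training with
the standard augmentation ranges (scale 0.9--1.1, translation +/-0.15,
rotation +/-0.02 of a turn), and 5 seeds for the occlusion-sweep ordering.
Occlusion sweeps are tested over 0--50% occlusion, the regime the model
family is characterized in; beyond ~60% the synthetic inputs lose nearly
all informative structure at 24 px and the variant ordering is no longer
stable.
Full-scale (100-category, 1000-epoch) training is protocol-compatible but
out of scope of the test suite.

## Known limitations

* The point-neuron constants, layer sizes and filter parameters are
  surrogates for unpublished originals; results should be read
  qualitatively at this scale.
* The fast within-cycle inhibition makes the activity bound exact but
  slightly sharpens transients relative to a purely equilibrium-placed
  kWTA.
* Settling is declared converged on a max-change tolerance over both
  activations and membrane potentials (default 0.001); non-convergence is
  flagged, not fatal.
* The CHL learner is sensitive to learning rate at small layer sizes;
  0.1 is stable on the fixtures but full-scale use would warrant a sweep.
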