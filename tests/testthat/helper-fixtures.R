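# Shared fixtures, built lazily and cached for the whole test run.
# Training runs use the default (study-condition) affine augmentation unless
# the property under test is independent of augmentation.

.fx <- new.env(parent = emptyenv())

fxMemo <- function(key, builder) {
  if (!exists(key, envir = .fx)) assign(key, builder(), envir = .fx)
  get(key, envir = .fx)
}

# 4-px complex-cell pooling: at the 24-px working size of the fixtures this
# puts receptive-field shifts on the scale of the augmentation jitter
fxBank <- function() fxMemo("bank", function() buildFilterBank(poolSize = 4))

# 5-category dataset used by most unit tests
fxDataset <- function() fxMemo("ds", function()
  makeSyntheticDataset(syntheticDatasetSpec(5, 3, 2, imageSize = 24, seed = 42)))

fxImages <- function() fxMemo("imgs", function() {
  ds <- fxDataset()
  lapply(seq_len(nrow(ds$manifest)), function(i) renderImage(ds, i))
})

# trained recurrent fixture: the cached seed-1 model of the sweep task
# (training is the expensive part of the suite, so it is shared)
fxTrainedNet <- function() fxSweepModels(1)$recurrent

# an untrained network of the same family, on the 5-category set
fxUntrainedNet <- function() fxMemo("untrainedNet", function() {
  ds <- fxDataset()
  spec <- kwtaNetworkSpec(fxBank(), 24, ds$categories, v2Size = 120, itSize = 80)
  buildNetwork(spec, seed = 1)
})

# ---- fixtures for the scaled replications (shared across test files) -------

# occlusion-sweep fixture: per seed, a trained recurrent net plus both
# backprop variants on a 4-category task; all 8 images are training items
fxSweepTask <- function() fxMemo("sweepTask", function()
  makeSyntheticDataset(syntheticDatasetSpec(4, 2, 1, imageSize = 24, seed = 11)))

# learning-efficacy fixture: the 10-category task trained by the recurrent
# and the sparse backprop learner, scored by 7-transform voting on the
# training manifest
fxLearningTask <- function() fxMemo("learningTask", function() {
  ds <- makeSyntheticDataset(syntheticDatasetSpec(10, 2, 2, imageSize = 24,
                                                  seed = 7))
  imgs <- lapply(seq_len(nrow(ds$manifest)), function(i) renderImage(ds, i))
  bank <- fxBank()
  spec <- kwtaNetworkSpec(bank, 24, ds$categories, v2Size = 200, itSize = 120)
  rec <- trainNetwork(buildNetwork(spec, seed = 1), ds, ds$manifest,
                      trainProtocol(epochs = 60, lrate = 0.05, seed = 2,
                                    voteEvery = 5, stopAccuracy = 92),
                      images = imgs)$net
  bps <- trainBpNetwork(
    buildBpNetwork("sparse", bank, 24, ds$categories, v2Size = 200,
                   itSize = 120, seed = 1),
    ds, ds$manifest, epochs = 250, seed = 2, stopAccuracy = 97,
    images = imgs)$bp
  list(dataset = ds, recurrent = rec, bpSparse = bps,
       recurrentAcc = as.numeric(evaluateAccuracy(rec, ds, ds$manifest,
                                                  "vote2d", seed = 55)),
       bpSparseAcc = as.numeric(evaluateAccuracy(bps, ds, ds$manifest,
                                                 "vote2d", seed = 55)))
})

# semantics fixture: clustered categories trained with and without semantic
# plus-phase clamping, plus the shaped pattern set and target matrix
fxSemanticsRun <- function() fxMemo("semanticsRun", function() {
  ds <- makeSyntheticDataset(syntheticDatasetSpec(6, 2, 1, imageSize = 24,
                                                  seed = 21))
  imgs <- lapply(seq_len(nrow(ds$manifest)), function(i) renderImage(ds, i))
  bank <- fxBank()
  target <- makeTargetDM(6, 3, within = 0.7, between = 0.15, seed = 22)
  patterns <- shapePatterns(initPatterns(6, 40, 0.25, seed = 23), target,
                            maxIters = 1200, seed = 24)
  spec <- kwtaNetworkSpec(bank, 24, ds$categories, v2Size = 120, itSize = 80,
                          semSize = 40)
  protWith <- trainProtocol(epochs = 20, lrate = 0.05, seed = 25,
                            useSemantics = TRUE)
  protWithout <- trainProtocol(epochs = 20, lrate = 0.05, seed = 25)
  with <- trainNetwork(buildNetwork(spec, seed = 26), ds, ds$manifest,
                       protWith, patterns = patterns, images = imgs)$net
  without <- trainNetwork(buildNetwork(spec, seed = 26), ds, ds$manifest,
                          protWithout, images = imgs)$net
  list(dataset = ds, patterns = patterns, target = target,
       netWith = with, netWithout = without,
       dmWith = categoryDM(with, ds, ds$manifest),
       dmWithout = categoryDM(without, ds, ds$manifest))
})

fxSweepModels <- function(seed) fxMemo(paste0("sweep", seed), function() {
  ds <- fxSweepTask()
  imgs <- lapply(seq_len(nrow(ds$manifest)), function(i) renderImage(ds, i))
  bank <- fxBank()
  spec <- kwtaNetworkSpec(bank, 24, ds$categories, v2Size = 120, itSize = 80)
  rec <- trainNetwork(buildNetwork(spec, seed = seed), ds, ds$manifest,
                      trainProtocol(epochs = 24, lrate = 0.05, seed = seed + 100,
                                    voteEvery = 4, stopAccuracy = 95),
                      images = imgs)$net
  # the backprop learners see few images per epoch, so they need many more
  # epochs than the recurrent learner to get a comparable presentation count
  bps <- trainBpNetwork(
    buildBpNetwork("sparse", bank, 24, ds$categories, v2Size = 120,
                   itSize = 80, seed = seed),
    ds, ds$manifest, epochs = 400, seed = seed + 100, stopAccuracy = 98,
    images = imgs)$bp
  bpd <- trainBpNetwork(
    buildBpNetwork("distrib", bank, 24, ds$categories, v2Size = 120,
                   itSize = 80, seed = seed),
    ds, ds$manifest, epochs = 400, seed = seed + 100, stopAccuracy = 98,
    images = imgs)$bp
  list(recurrent = rec, noFeedback = lesionFeedback(rec),
       bpSparse = bps, bpDistrib = bpd)
})
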