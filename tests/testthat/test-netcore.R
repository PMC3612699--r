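# independent equilibrium oracle: membrane potential each unit settles to
# under fixed conductances, from the zero-derivative condition
eqVm <- function(ge, gi, pm = defaultNetParams()) {
  (ge * pm$eRev + gi * pm$iRev + pm$gLeak * pm$lRev) / (ge + gi + pm$gLeak)
}

test_that("network construction is deterministic, bounded and validated", {
  ds <- fxDataset()
  spec <- kwtaNetworkSpec(fxBank(), 24, ds$categories, v2Size = 50, itSize = 30)
  n1 <- buildNetwork(spec, seed = 9)
  n2 <- buildNetwork(spec, seed = 9)
  expect_identical(projectionWeights(n1, "V1", "V2"),
                   projectionWeights(n2, "V1", "V2"))
  for (pr in n1@projections)
    expect_true(min(pr$W) >= 0 && max(pr$W) <= 1)
  # semantics layer is optional
  expect_false("Semantics" %in% layerNames(n1))
  specSem <- kwtaNetworkSpec(fxBank(), 24, ds$categories, v2Size = 50,
                             itSize = 30, semSize = 20)
  expect_true("Semantics" %in% layerNames(buildNetwork(specSem, 1)))
  # every hidden feedforward projection has a feedback twin; V1 gets none
  ff <- vapply(n1@projections, function(p) paste(p$from, p$to), character(1))
  expect_true("IT V2" %in% ff && "Output IT" %in% ff)
  expect_false(any(grepl(" V1$", ff)))
  bad <- spec; bad$v2Size <- 3; bad$kwtaPct <- 2
  expect_error(buildNetwork(bad, 1), "k exceeds")
})

test_that("kWTA inhibition lands between the k-th and (k+1)-th threshold conductances", {
  pm <- defaultNetParams()
  set.seed(31)
  for (case in 1:1000) {
    ge <- runif(20, 0, 1)
    k <- sample(1:10, 1)
    gi <- kwtaInhibition(ge, k, pm)
    # brute-force oracle: compute each unit's threshold conductance directly
    gThr <- (ge * (pm$eRev - pm$theta) + pm$gLeak * (pm$lRev - pm$theta)) /
      (pm$theta - pm$iRev)
    srt <- sort(gThr, decreasing = TRUE)
    expect_gte(gi, max(0, srt[k + 1]) - 1e-12)
    expect_lte(gi, max(0, srt[k]) + 1e-12)
    # at equilibrium under this inhibition, at most k units exceed threshold
    expect_lte(sum(eqVm(ge, gi, pm) > pm$theta), k)
  }
})

test_that("kWTA winner count is exact for distinct drives and degenerate cases are sane", {
  pm <- defaultNetParams()
  # the example case: one clear winner
  ge <- c(0.9, 0.5, 0.1, 0.05)
  gi <- kwtaInhibition(ge, 1, pm)
  above <- eqVm(ge, gi, pm) > pm$theta
  expect_identical(which(above), 1L)
  # all drives equal: degenerate tie resolves all-or-none (here: none above)
  geTie <- rep(0.5, 6)
  giTie <- kwtaInhibition(geTie, 2, pm)
  expect_true(sum(eqVm(geTie, giTie, pm) > pm$theta) %in% c(0, 6))
  # k >= n: inhibition below the weakest unit, nobody suppressed
  giAll <- kwtaInhibition(ge, 4, pm)
  gThr <- (ge * (pm$eRev - pm$theta) + pm$gLeak * (pm$lRev - pm$theta)) /
    (pm$theta - pm$iRev)
  expect_lte(giAll, min(gThr))
  expect_error(kwtaInhibition(ge, 0, pm), ">= 1")
})

test_that("activation and winner-count bounds hold at every cycle for random inputs", {
  net <- fxUntrainedNet()
  imgs <- fxImages()
  for (i in c(1, 9, 23)) {
    run <- settle(net, v1Clamp(net, imgs[[i]]), record = TRUE)
    for (snap in run$snapshots) {
      for (nm in names(snap)) {
        expect_true(all(snap[[nm]] >= 0 & snap[[nm]] <= 1))
        k <- net@layers$k[match(nm, net@layers$name)]
        expect_lte(sum(snap[[nm]] > 0.5), k)
      }
    }
  }
})

test_that("with zero drive the network decays to the leak potential", {
  net <- fxUntrainedNet()
  st <- initState(net)
  for (cy in 1:30) st <- updateCycle(net, st, clamps = list(V1 = rep(0, layerSize(net, "V1"))))
  for (nm in c("V2", "IT", "Output")) {
    expect_equal(st[[nm]]$vm, rep(net@params$lRev, layerSize(net, nm)),
                 tolerance = 1e-6)
    expect_true(all(st[[nm]]$act < 1e-10))
  }
})

test_that("settling reaches a stable fixed point and stops there", {
  net <- fxTrainedNet()
  cl <- v1Clamp(net, renderImage(fxSweepTask(), 1))
  run <- settle(net, cl)
  expect_true(run$converged)
  expect_lte(run$cycles, net@params$maxCycles)
  # from the converged state, further settling changes nothing beyond tol
  again <- settle(net, cl, state = run$state)
  expect_lte(again$cycles, 2)
  expect_true(again$converged)
  for (nm in names(run$state))
    expect_equal(again$state[[nm]]$act, run$state[[nm]]$act,
                 tolerance = net@params$tol * 2)
})

test_that("feedback lesion silences top-down influence exactly and is restorable", {
  net <- fxTrainedNet()
  les <- lesionFeedback(net)
  img <- renderImage(fxSweepTask(), 3)
  cl <- v1Clamp(net, img)
  # with feedback silenced, lower layers are invariant to any perturbation
  # of strictly higher layers
  stA <- initState(les)
  stB <- initState(les)
  stB$Output$act <- rep(1, layerSize(les, "Output"))
  stB$Output$vm <- rep(0.9, layerSize(les, "Output"))
  for (cy in 1:10) {
    stA <- updateCycle(les, stA, cl)
    stB <- updateCycle(les, stB, cl)
    expect_identical(stA$V2, stB$V2)
    expect_identical(stA$IT, stB$IT)
    stB$Output <- list(vm = stB$Output$vm + 0.01, act = stB$Output$act)
  }
  # restoring reproduces the original behavior bit-exactly
  rest <- restoreFeedback(les)
  s1 <- settle(net, cl); s2 <- settle(rest, cl)
  expect_identical(s1$state, s2$state)
  expect_false(identical(settle(les, cl)$state$V2, s1$state$V2))
})

test_that("inhibition renormalizes weak inputs: winner sets are preserved under input halving", {
  # halving the input layer activations halves raw excitatory drive, but the
  # kWTA inhibition tracks it, so downstream winner sets overlap strongly
  net <- fxTrainedNet()
  cl <- v1Clamp(net, renderImage(fxSweepTask(), 5))
  half <- list(V1 = cl$V1 * 0.5)
  w1 <- which(settle(net, cl)$state$V2$act > 0.5)
  w2 <- which(settle(net, half)$state$V2$act > 0.5)
  jaccard <- length(intersect(w1, w2)) / length(union(w1, w2))
  expect_gte(jaccard, 0.5)
})
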