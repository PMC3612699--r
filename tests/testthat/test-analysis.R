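test_that("cosine similarity matches closed forms", {
  expect_equal(cosineSim(c(2, 1), c(2, 1)), 1)
  expect_equal(cosineSim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSim(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosineSim(numeric(3), c(1, 2, 3)), 0)
})

test_that("unoccluded completion trajectories converge to 1 in every layer", {
  net <- fxTrainedNet()
  traj <- completionTrajectory(net, renderImage(fxSweepTask(), 1), O = 0)
  finals <- tapply(traj$cosine, traj$layer,
                   function(x) x[length(x)])
  expect_true(all(abs(finals - 1) < 1e-6))
})

test_that("majority voting follows the strict-majority and tie rules", {
  mk <- function(votes, sums, cats = c("a", "b", "c"))
    structure(list(votes = votes, winner = ReVis:::tallyWinner(votes, sums, cats)$winner,
                   activationSums = stats::setNames(sums, cats), tie = FALSE),
              class = "VoteResult")
  cats <- c("a", "b", "c")
  # strict majority
  t1 <- ReVis:::tallyWinner(c("a", "a", "a", "a", "b", "b", "b"),
                            c(3, 3, 0), cats)
  expect_equal(t1$winner, "a")
  expect_false(t1$tie)
  # tie broken by summed activation
  t2 <- ReVis:::tallyWinner(c("a", "a", "b", "b"), c(2.1, 1.9, 0), cats)
  expect_equal(t2$winner, "a")
  expect_true(t2$tie)
  t3 <- ReVis:::tallyWinner(c("a", "a", "b", "b"), c(1.9, 2.1, 0), cats)
  expect_equal(t3$winner, "b")
  # residual tie: lowest category index
  t4 <- ReVis:::tallyWinner(c("a", "b"), c(1, 1, 0), cats)
  expect_equal(t4$winner, "a")

  # second-order vote: modal first-order winner
  vr <- list(mk("a", c(1, 0, 0)), mk("a", c(1, 0, 0)), mk("b", c(0, 1, 0)))
  expect_equal(secondOrderVote(vr), "a")
  expect_error(secondOrderVote(list()), "empty")
})

test_that("single-presentation vote equals the single-trial argmax", {
  net <- fxTrainedNet()
  img <- renderImage(fxSweepTask(), 2)
  vr <- voteRecognition(net, img, nPresentations = 1,
                        augment = identityAffineRanges(), seed = 3)
  out <- settle(net, v1Clamp(net, img))$state$Output$act
  expect_equal(vr$winner, net@categories[which.max(out)])
  expect_length(vr$votes, 1)
})

test_that("vote determinism and occlusion mask sharing across presentations", {
  net <- fxTrainedNet()
  img <- renderImage(fxSweepTask(), 4)
  v1 <- voteRecognition(net, img, O = 0.5, seed = 12)
  v2 <- voteRecognition(net, img, O = 0.5, seed = 12)
  expect_identical(v1, v2)
})

test_that("evaluateAccuracy scores memorized items and validates input", {
  net <- fxTrainedNet()
  ds <- fxSweepTask()
  acc <- evaluateAccuracy(net, ds, ds$manifest, "none", seed = 4)
  expect_true(as.numeric(acc) >= 0 && as.numeric(acc) <= 100)
  expect_equal(attr(acc, "n"), 8)
  expect_error(evaluateAccuracy(net, ds, ds$manifest[0, ], "none"), "empty")
  # full mode scores per exemplar
  accF <- evaluateAccuracy(net, ds, ds$manifest, "full", seed = 4)
  expect_equal(attr(accF, "n"), 8)   # 4 categories x 2 exemplars
})

test_that("distance-matrix correlation is a permutation-invariant off-diagonal Pearson", {
  set.seed(10)
  dm1 <- makeTargetDM(8, 2, noise = 0.1, seed = 1)
  expect_equal(dmCorrelation(dm1, dm1), 1)
  expect_equal(dmCorrelation(dm1, 1 - dm1), -1)
  dm2 <- makeTargetDM(8, 4, noise = 0.2, seed = 2)
  perm <- sample(8)
  expect_equal(dmCorrelation(dm1, dm2),
               dmCorrelation(dm1[perm, perm], dm2[perm, perm]),
               tolerance = 1e-12)
  expect_error(dmCorrelation(dm1, matrix(1, 3, 3)), "shape")
  expect_error(dmCorrelation(matrix(1, 3, 3), matrix(1, 3, 3)), "constant")
})

test_that("category distance matrices are symmetric with unit diagonal", {
  net <- fxTrainedNet()
  ds <- fxSweepTask()
  dm <- categoryDM(net, ds, ds$manifest)
  expect_true(isSymmetric(dm))
  expect_equal(unname(diag(dm)), rep(1, 4))
  expect_true(all(dm >= 0 & dm <= 1))
  expect_error(categoryDM(net, ds, ds$manifest[1:4, ]), "no test items")
})

test_that("voting does not hurt accuracy when single trials beat chance", {
  # across seeds, 7-vote accuracy should be at least single-trial accuracy
  net <- fxTrainedNet()
  ds <- fxSweepTask()
  man <- ds$manifest
  single <- vapply(1:3, function(s)
    as.numeric(evaluateAccuracy(net, ds, man, "none", seed = s)), numeric(1))
  voted <- vapply(1:3, function(s)
    as.numeric(evaluateAccuracy(net, ds, man, "vote2d", seed = s)), numeric(1))
  expect_gte(mean(voted) + 5, mean(single))   # allow sampling noise
})

test_that("semantic inference ranks the trained category's pattern highly", {
  fx <- fxSemanticsRun()
  ds <- fx$dataset
  hits <- 0
  probe <- seq(1, nrow(ds$manifest), by = 2)   # one exemplar per category
  for (i in probe) {
    row <- ds$manifest[i, ]
    si <- semanticInference(fx$netWith, renderImage(ds, row), fx$patterns)
    expect_setequal(si$ranking, fx$netWith@categories)
    expect_true(all(si$trajectory$cosine >= -1 & si$trajectory$cosine <= 1))
    hits <- hits + (match(row$category, si$ranking) <= 2)
  }
  # trained categories' canonical patterns dominate the free semantics state
  expect_gte(hits, length(probe) - 2)
  expect_error(semanticInference(fxTrainedNet(), renderImage(ds, 1), fx$patterns),
               "no Semantics layer")
})
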