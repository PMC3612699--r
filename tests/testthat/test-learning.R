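test_that("CHL deltas vanish when phases match and follow the closed form", {
  W <- matrix(runif(12, 0.2, 0.8), 3, 4)
  x <- runif(3); y <- runif(4)
  expect_equal(chlUpdate(W, x, x, y, y, lrate = 0.5, hebbMix = 0), W)
  # closed form: x-=y-=0, x+=y+=1, eps=0.1, w=0.5 -> +0.05 after soft bounding
  expect_equal(chlUpdate(matrix(0.5), 0, 1, 0, 1, lrate = 0.1, hebbMix = 0),
               matrix(0.55))
  # pure Hebbian term is zero when x+ equals the weight
  expect_equal(chlUpdate(matrix(0.3), 0.7, 0.3, 0, 1, lrate = 0.1, hebbMix = 1),
               matrix(0.3))
})

test_that("soft bounding keeps weights in [0,1] under any update sequence", {
  set.seed(4)
  W <- matrix(runif(25), 5, 5)
  for (i in 1:200) {
    W <- chlUpdate(W, runif(5), runif(5), runif(5), runif(5),
                   lrate = runif(1, 0, 2), hebbMix = runif(1))
    expect_true(min(W) >= 0 && max(W) <= 1)
  }
})

test_that("CHL preserves weight symmetry for reciprocal projections", {
  # swapping sender/receiver phase roles transposes the delta, so symmetric
  # initial weights stay symmetric
  set.seed(5)
  W <- matrix(runif(16, 0.3, 0.7), 4, 4); W <- (W + t(W)) / 2
  xm <- runif(4); xp <- runif(4); ym <- runif(4); yp <- runif(4)
  fwd <- chlUpdate(W, xm, xp, ym, yp, lrate = 0.2, hebbMix = 0)
  bwd <- chlUpdate(t(W), ym, yp, xm, xp, lrate = 0.2, hebbMix = 0)
  expect_equal(fwd, t(bwd), tolerance = 1e-12)
})

test_that("cross-entropy value, gating and clipping behave as specified", {
  # t = 1, o = 0.5: CE = -log 0.5
  ce <- crossEntropy(1, 0.5, tolerance = 0.05)
  expect_equal(ce$value, 0.6931, tolerance = 1e-4)
  expect_true(ce$grad < 0)
  # within tolerance: zero gradient everywhere, loss still defined
  ce2 <- crossEntropy(c(1, 0), c(0.96, 0.04), tolerance = 0.05)
  expect_equal(ce2$grad, c(0, 0))
  expect_gt(ce2$value, 0)
  # matched outputs: no gradient
  expect_equal(crossEntropy(0.4, 0.4, 0.05)$grad, 0)
  # clipping at the boundaries keeps the loss finite
  expect_true(is.finite(crossEntropy(1, 0, 0.05)$value))
  expect_true(is.finite(crossEntropy(0, 1, 0.05)$value))
})

test_that("backprop variants carry their printed parameter bundles", {
  ds <- fxDataset()
  sp <- buildBpNetwork("sparse", fxBank(), 24, ds$categories, v2Size = 40,
                       itSize = 30, seed = 3)
  di <- buildBpNetwork("distrib", fxBank(), 24, ds$categories, v2Size = 40,
                       itSize = 30, seed = 3)
  expect_equal(sp@lrate, 0.2)
  expect_equal(di@lrate, 0.01)
  expect_true(all(unlist(sp@biases) == -3))
  expect_true(all(unlist(di@biases) == 0))
  # same seed, same variant: identical initialization
  sp2 <- buildBpNetwork("sparse", fxBank(), 24, ds$categories, v2Size = 40,
                        itSize = 30, seed = 3)
  expect_identical(sp@weights, sp2@weights)
  # sparse variant starts with far lower hidden activity than distrib
  img <- fxImages()[[1]]
  hidSp <- bpForward(sp, ReVis:::bpEncode(sp, img))[[2]]
  hidDi <- bpForward(di, ReVis:::bpEncode(di, img))[[2]]
  expect_lt(mean(hidSp), mean(hidDi) / 3)
})

test_that("backprop gradients agree with central finite differences", {
  set.seed(8)
  sizes <- c(6, 5, 4, 3)
  bank <- fxBank()
  bp <- buildBpNetwork("distrib", bank, 24, letters[1:3], v2Size = 5,
                       itSize = 4, tolerance = 0, seed = 1)
  # shrink to a toy net so finite differences are cheap
  bp@sizes <- as.integer(sizes)
  bp@weights <- lapply(1:3, function(i)
    matrix(rnorm(sizes[i] * sizes[i + 1], 0, 0.5), sizes[i], sizes[i + 1]))
  bp@biases <- lapply(sizes[-1], function(n) rnorm(n, 0, 0.1))
  input <- runif(6)
  target <- c(1, 0, 0)
  loss <- function(b) {
    out <- bpForward(b, input)[[4]]
    crossEntropy(target, out, tolerance = 0)$value
  }
  tr <- bpTrainTrial(bp, input, target, lrate = 1)
  analytic <- lapply(1:3, function(i) bp@weights[[i]] - tr$bp@weights[[i]])
  h <- 1e-5
  for (i in 1:3) {
    numeric <- bp@weights[[i]] * 0
    for (j in seq_along(numeric)) {
      bPlus <- bp; bPlus@weights[[i]][j] <- bPlus@weights[[i]][j] + h
      bMinus <- bp; bMinus@weights[[i]][j] <- bMinus@weights[[i]][j] - h
      numeric[j] <- (loss(bPlus) - loss(bMinus)) / (2 * h)
    }
    expect_equal(analytic[[i]], numeric, tolerance = 1e-4)
  }
})

test_that("backprop learns a separable toy and the tolerance gates updates", {
  set.seed(9)
  bank <- fxBank()
  bp <- buildBpNetwork("sparse", bank, 24, c("a", "b"), v2Size = 20,
                       itSize = 10, seed = 2)
  inputA <- c(rep(0.9, 10), rep(0, v1Size(bank, 24) - 10))
  inputB <- c(rep(0, v1Size(bank, 24) - 10), rep(0.9, 10))
  # the strong negative biases make early gradients tiny, so the toy needs a
  # few hundred passes before the outputs differentiate
  losses <- numeric(300)
  for (ep in 1:300) {
    trA <- bpTrainTrial(bp, inputA, c(1, 0)); bp <- trA$bp
    trB <- bpTrainTrial(bp, inputB, c(0, 1)); bp <- trB$bp
    losses[ep] <- trA$loss + trB$loss
  }
  smoothed <- stats::filter(losses, rep(1 / 5, 5), sides = 1)
  expect_lt(tail(stats::na.omit(smoothed), 1), smoothed[5])
  expect_true(trA <- bpTrainTrial(bp, inputA, c(1, 0))$correct)

  # tolerance 1.0: every error is within tolerance, so nothing updates
  bpT <- buildBpNetwork("sparse", bank, 24, c("a", "b"), v2Size = 20,
                        itSize = 10, tolerance = 1, seed = 2)
  up <- bpTrainTrial(bpT, inputA, c(1, 0))
  expect_identical(up$bp@weights, bpT@weights)
})

test_that("two-phase training leaves weights unchanged at zero learning rate", {
  ds <- fxDataset()
  net <- fxUntrainedNet()
  prot <- trainProtocol(epochs = 1, lrate = 0, seed = 6)
  tr <- trainNetwork(net, ds, ds$manifest[1:4, ], prot,
                     images = fxImages()[1:4])
  expect_identical(tr$net@projections, net@projections)
  expect_error(trainTrial(net, fxImages()[[1]], "nope", prot), "unknown category")
})

test_that("the recurrent learner memorizes its training set", {
  lt <- fxLearningTask()
  ds <- lt$dataset
  acc <- evaluateAccuracy(lt$recurrent, ds, ds$manifest[1:20, ],
                          voteMode = "vote2d", seed = 77)
  expect_gte(as.numeric(acc), 90)
})
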