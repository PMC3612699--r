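#' @include v1.R netcore.R
NULL

#' Contrastive Hebbian weight update
#'
#' Two-phase error-driven rule over minus-phase (inputs clamped, outputs
#' free) and plus-phase (inputs and targets clamped) activations:
#' \deqn{\Delta w = \epsilon [(1-m)(x^+ y^+ - x^- y^-) + m\, y^+ (x^+ - w)]}
#' with a small Hebbian mix \code{m}. Soft weight bounding scales increases
#' by \code{(1 - w)} and decreases by \code{w}, keeping weights in
#' \code{[0,1]} under any update sequence.
#'
#' @param W Sender x receiver weight matrix.
#' @param xMinus,xPlus Sender activations in the two phases.
#' @param yMinus,yPlus Receiver activations in the two phases.
#' @param lrate Learning rate \code{epsilon}.
#' @param hebbMix Hebbian mix coefficient in \code{[0,1]} (default 0.01).
#' @return Updated weight matrix.
#' @examples
#' chlUpdate(matrix(0.5), 0, 1, 0, 1, lrate = 0.1, hebbMix = 0)  # 0.55
#' @export
chlUpdate <- function(W, xMinus, xPlus, yMinus, yPlus, lrate, hebbMix = 0.01) {
  err <- tcrossprod(xPlus, yPlus) - tcrossprod(xMinus, yMinus)
  hebb <- (xPlus - W) * rep(yPlus, each = nrow(W))
  dwt <- lrate * ((1 - hebbMix) * err + hebbMix * hebb)
  # soft bounding keeps steps proportional to the remaining range; the final
  # clamp guards the invariant for extreme learning rates (|dwt| > 1)
  matrix(pmin(1, pmax(0, W + ifelse(dwt > 0, dwt * (1 - W), dwt * W))),
         nrow(W), ncol(W))
}

#' Training protocol for the recurrent network
#'
#' @param epochs Number of passes over the training manifest.
#' @param lrate Learning rate (default 0.1).
#' @param hebbMix Hebbian mix coefficient (default 0.01).
#' @param augment Affine augmentation ranges applied at every presentation
#'   (default \code{\link{defaultAffineRanges}}).
#' @param useSemantics Clamp the semantic pattern alongside the category
#'   target in the plus phase (requires a Semantics layer and patterns).
#' @param voteEvery Voting cadence: every \code{voteEvery} epochs, evaluate
#'   7-transform voted accuracy on the training manifest and log it;
#'   \code{NULL} disables periodic voting.
#' @param stopAccuracy Stop early once accuracy reaches this percentage
#'   (voted accuracy when \code{voteEvery} is set, otherwise within-epoch
#'   minus-phase accuracy); \code{NULL} to always run all epochs.
#' @param seed Integer seed for presentation order and augmentation draws.
#' @return Protocol list.
#' @export
trainProtocol <- function(epochs = 20, lrate = 0.1, hebbMix = 0.01,
                          augment = defaultAffineRanges(), useSemantics = FALSE,
                          voteEvery = NULL, stopAccuracy = NULL, seed = 1) {
  stopifnot(lrate >= 0, hebbMix >= 0, hebbMix <= 1, epochs >= 1)
  list(epochs = epochs, lrate = lrate, hebbMix = hebbMix, augment = augment,
       useSemantics = useSemantics, voteEvery = voteEvery,
       stopAccuracy = stopAccuracy, seed = as.integer(seed))
}

#' One two-phase training trial
#'
#' Augments the image, encodes it through the front-end, settles the minus
#' phase (V1 clamped), then the plus phase (V1, the one-hot category output
#' and optionally the semantic pattern clamped, starting from the minus
#' state), and applies \code{\link{chlUpdate}} to every projection
#' (feedback projections learn too).
#'
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @param img Normalized image matrix.
#' @param category True category label.
#' @param protocol A \code{\link{trainProtocol}}.
#' @param semPattern Optional binary semantic pattern to clamp in the plus
#'   phase.
#' @param affineParams Optional pre-drawn affine parameters (otherwise drawn
#'   from the protocol's ranges using the current RNG stream).
#' @return List: \code{net} (updated), \code{correct} (was the minus-phase
#'   winner the true category), \code{cycles} (minus-phase settling cycles).
#' @export
trainTrial <- function(net, img, category, protocol, semPattern = NULL,
                       affineParams = NULL) {
  if (!category %in% net@categories) stop("unknown category: ", category)
  if (is.null(affineParams)) affineParams <- sampleAffine(1, protocol$augment)
  pres <- applyAffine(img, affineParams)
  clampMinus <- v1Clamp(net, pres)
  minus <- settle(net, clampMinus)
  winner <- whichMax1(minus$state$Output$act)
  clampPlus <- clampMinus
  clampPlus$Output <- outputClamp(net, category)
  if (!is.null(semPattern) && "Semantics" %in% layerNames(net))
    clampPlus$Semantics <- as.numeric(semPattern)
  plus <- settle(net, clampPlus, state = minus$state)
  mAct <- lapply(minus$state, `[[`, "act")
  pAct <- lapply(plus$state, `[[`, "act")
  if (protocol$lrate > 0) {
    net@projections <- lapply(net@projections, function(pr) {
      pr$W <- chlUpdate(pr$W, mAct[[pr$from]], pAct[[pr$from]],
                        mAct[[pr$to]], pAct[[pr$to]],
                        protocol$lrate, protocol$hebbMix)
      pr
    })
  }
  list(net = net, correct = net@categories[winner] == category,
       cycles = minus$cycles)
}

#' Train a recurrent network on a manifest
#'
#' Runs epochs of two-phase trials over the (shuffled) training manifest
#' with per-presentation affine augmentation. Per-epoch minus-phase accuracy
#' and mean settling cycles are logged.
#'
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @param dataset Dataset from \code{\link{makeSyntheticDataset}} (or a list
#'   with a compatible \code{spec} and \code{categories}).
#' @param manifest Training manifest rows.
#' @param protocol A \code{\link{trainProtocol}}.
#' @param patterns Optional \code{\linkS4class{SemanticPatternSet}} whose
#'   rows (by category index) are clamped in the plus phase when
#'   \code{protocol$useSemantics} is TRUE.
#' @param images Optional list of pre-rendered images indexed like
#'   \code{manifest} rows (avoids re-rendering each epoch).
#' @return List: \code{net} (trained; when a voting cadence is set, the
#'   snapshot with the best voted accuracy), \code{log} (data frame with
#'   \code{epoch}, \code{trainAcc}, \code{meanCycles}, \code{voteAcc}).
#' @export
trainNetwork <- function(net, dataset, manifest, protocol, patterns = NULL,
                         images = NULL) {
  if (is.null(images))
    images <- lapply(seq_len(nrow(manifest)), function(i)
      renderImage(dataset, manifest[i, ]))
  log <- data.frame(epoch = integer(), trainAcc = numeric(),
                    meanCycles = numeric(), voteAcc = numeric())
  bestNet <- net; bestVote <- -Inf
  withSeed(protocol$seed, {
    for (ep in seq_len(protocol$epochs)) {
      ord <- sample.int(nrow(manifest))
      nCorrect <- 0; cyc <- 0
      for (i in ord) {
        cat_i <- manifest$category[i]
        sem <- if (protocol$useSemantics && !is.null(patterns))
          patternFor(patterns, match(cat_i, net@categories)) else NULL
        tr <- trainTrial(net, images[[i]], cat_i, protocol, semPattern = sem)
        net <- tr$net
        nCorrect <- nCorrect + tr$correct
        cyc <- cyc + tr$cycles
      }
      acc <- 100 * nCorrect / nrow(manifest)
      voteAcc <- NA_real_
      if (!is.null(protocol$voteEvery) && ep %% protocol$voteEvery == 0) {
        voteAcc <- as.numeric(evaluateAccuracy(
          net, dataset, manifest, voteMode = "vote2d",
          augment = protocol$augment, seed = protocol$seed + ep))
        if (voteAcc > bestVote) { bestVote <- voteAcc; bestNet <- net }
      }
      log <- rbind(log, data.frame(epoch = ep, trainAcc = acc,
                                   meanCycles = cyc / nrow(manifest),
                                   voteAcc = voteAcc))
      stopMetric <- if (!is.null(protocol$voteEvery)) voteAcc else acc
      if (!is.null(protocol$stopAccuracy) && !is.na(stopMetric) &&
          stopMetric >= protocol$stopAccuracy) break
    }
  })
  list(net = if (is.null(protocol$voteEvery)) net else bestNet, log = log)
}

#' Cross-entropy error with an error tolerance
#'
#' Loss \code{CE = -sum(t log o + (1 - t) log(1 - o))}. Output units whose
#' absolute error \code{|t - o|} is at or below \code{tolerance} contribute
#' zero gradient (they do not drive learning); the loss value itself is not
#' gated. Outputs at exactly 0 or 1 are clipped to machine epsilon.
#'
#' @param t Target vector in \code{[0,1]}.
#' @param o Output vector in \code{(0,1)}.
#' @param tolerance Error tolerance (default 0.05).
#' @return List: \code{value} (scalar loss), \code{grad} (dCE/do per unit,
#'   tolerance-gated), \code{delta} (tolerance-gated \code{o - t}, the
#'   pre-sigmoid gradient used by backpropagation).
#' @export
crossEntropy <- function(t, o, tolerance = 0.05) {
  stopifnot(length(t) == length(o))
  eps <- .Machine$double.eps
  oc <- pmin(1 - eps, pmax(eps, o))
  value <- -sum(t * log(oc) + (1 - t) * log(1 - oc))
  gate <- abs(t - o) > tolerance
  grad <- ifelse(gate, (oc - t) / (oc * (1 - oc)), 0)
  list(value = value, grad = grad, delta = ifelse(gate, oc - t, 0))
}

# -- backpropagation comparison networks -------------------------------------

#' BpNetwork: feedforward backpropagation comparison network
#'
#' Same layer structure as the recurrent network but purely feedforward
#' (V1 -> V2 -> IT -> Output) with logistic units, trained by
#' backpropagation of tolerance-gated cross-entropy error, plain SGD (no
#' momentum, no weight decay). Two printed parameter bundles:
#' \describe{
#'   \item{sparse}{bias weights initialized to -3.0 (strongly reducing
#'     initial activity), learning rate 0.2, kWTA-filtered V1 input.}
#'   \item{distrib}{bias weights 0, learning rate 0.01, raw (dense) V1
#'     filter outputs, producing highly distributed activity.}
#' }
#'
#' @slot variant "sparse" or "distrib".
#' @slot weights,biases Per-connection weight matrices and per-layer biases.
#' @slot sizes Layer unit counts (V1, V2, IT, Output).
#' @slot lrate Learning rate.
#' @slot tolerance Cross-entropy error tolerance.
#' @slot bank,imageSize,kwtaPct Front-end configuration (kwtaPct is NA for
#'   the distrib variant, which bypasses front-end kWTA).
#' @slot categories Category labels.
#' @slot seed Initialization seed.
#' @export
setClass("BpNetwork",
  representation(variant = "character", weights = "list", biases = "list",
                 sizes = "integer", lrate = "numeric", tolerance = "numeric",
                 bank = "FilterBank", imageSize = "integer",
                 kwtaPct = "numeric", categories = "character",
                 seed = "integer"),
  validity = function(object) {
    if (!object@variant %in% c("sparse", "distrib"))
      return("variant must be 'sparse' or 'distrib'")
    if (length(object@weights) != length(object@sizes) - 1)
      return("one weight matrix per successive layer pair required")
    TRUE
  })

setMethod("show", "BpNetwork", function(object) {
  cat("BpNetwork (", object@variant, "): ",
      paste(object@sizes, collapse = " -> "),
      ", lrate ", object@lrate, "\n", sep = "")
})

#' Build a backpropagation comparison network
#'
#' Weights are uniform zero-mean with 0.5 variability; biases and learning
#' rate follow the variant bundle exactly (sparse: -3.0 / 0.2; distrib:
#' 0 / 0.01). The distrib variant reads the dense (non-kWTA) V1 responses.
#'
#' @param variant "sparse" or "distrib".
#' @param bank Front-end \code{\linkS4class{FilterBank}}.
#' @param imageSize Working image size in pixels.
#' @param categories Category labels.
#' @param v2Size,itSize Hidden layer sizes (mirror the recurrent network's).
#' @param kwtaPct Front-end sparsity for the sparse variant (default 0.15).
#' @param tolerance Error tolerance (default 0.05).
#' @param seed Integer seed.
#' @return A \code{\linkS4class{BpNetwork}}.
#' @export
buildBpNetwork <- function(variant = c("sparse", "distrib"), bank, imageSize,
                           categories, v2Size = 120, itSize = 80,
                           kwtaPct = 0.15, tolerance = 0.05, seed = 1) {
  variant <- match.arg(variant)
  sizes <- c(v1Size(bank, imageSize), v2Size, itSize, length(categories))
  biasInit <- if (variant == "sparse") -3.0 else 0
  lrate <- if (variant == "sparse") 0.2 else 0.01
  withSeed(seed, {
    weights <- lapply(seq_len(length(sizes) - 1), function(i)
      matrix(runif(sizes[i] * sizes[i + 1], -0.5, 0.5), sizes[i], sizes[i + 1]))
    biases <- lapply(sizes[-1], function(n) rep(biasInit, n))
    new("BpNetwork", variant = variant, weights = weights, biases = biases,
        sizes = as.integer(sizes), lrate = lrate, tolerance = tolerance,
        bank = bank, imageSize = as.integer(imageSize),
        kwtaPct = if (variant == "sparse") kwtaPct else NA_real_,
        categories = as.character(categories), seed = as.integer(seed))
  })
}

#' Forward pass of a backpropagation network
#' @param bp A \code{\linkS4class{BpNetwork}}.
#' @param input V1 input vector (already encoded).
#' @return List of per-layer activations (input first).
#' @export
bpForward <- function(bp, input) {
  acts <- list(as.numeric(input))
  for (i in seq_along(bp@weights)) {
    z <- as.numeric(crossprod(bp@weights[[i]], acts[[i]])) + bp@biases[[i]]
    acts[[i + 1]] <- plogis(z)
  }
  acts
}

# encode an image for a bp net per its variant
bpEncode <- function(bp, img) {
  v1Vector(v1Encode(img, bp@bank, if (bp@variant == "sparse") bp@kwtaPct
                    else NA), raw = bp@variant == "distrib")
}

#' One backpropagation training trial
#'
#' Forward pass, tolerance-gated cross-entropy at the output, gradient
#' backpropagation through the logistic units, and a plain SGD weight and
#' bias update.
#'
#' @param bp A \code{\linkS4class{BpNetwork}}.
#' @param input Encoded V1 input vector.
#' @param target Target output vector (one-hot for classification).
#' @param lrate Learning rate override (default: the network's).
#' @return List: \code{bp} (updated), \code{loss}, \code{correct}.
#' @export
bpTrainTrial <- function(bp, input, target, lrate = bp@lrate) {
  acts <- bpForward(bp, input)
  out <- acts[[length(acts)]]
  ce <- crossEntropy(target, out, bp@tolerance)
  if (!is.finite(ce$value))
    stop("divergence: non-finite loss (max |output| = ", max(abs(out)), ")")
  nW <- length(bp@weights)
  deltas <- vector("list", nW)          # dCE/dz for layer i + 1
  deltas[[nW]] <- ce$delta              # CE + logistic output shortcut
  for (i in rev(seq_len(nW - 1))) {
    a <- acts[[i + 1]]
    deltas[[i]] <- as.numeric(bp@weights[[i + 1]] %*% deltas[[i + 1]]) *
      a * (1 - a)
  }
  for (i in seq_len(nW)) {
    bp@weights[[i]] <- bp@weights[[i]] - lrate * tcrossprod(acts[[i]], deltas[[i]])
    bp@biases[[i]] <- bp@biases[[i]] - lrate * deltas[[i]]
  }
  list(bp = bp, loss = ce$value,
       correct = whichMax1(out) == whichMax1(target))
}

#' Train a backpropagation network on a manifest
#'
#' @param bp A \code{\linkS4class{BpNetwork}}.
#' @param dataset Dataset from \code{\link{makeSyntheticDataset}}.
#' @param manifest Training manifest rows.
#' @param epochs Number of epochs.
#' @param augment Affine augmentation ranges.
#' @param stopAccuracy Optional early-stop accuracy percentage; training
#'   stops after two consecutive qualifying epochs (a single small epoch can
#'   clear the bar by luck under augmentation).
#' @param seed Integer seed for order/augmentation.
#' @param images Optional pre-rendered image list.
#' @return List: \code{bp} (trained), \code{log} (epoch, trainAcc, meanLoss).
#' @export
trainBpNetwork <- function(bp, dataset, manifest, epochs = 20,
                           augment = defaultAffineRanges(),
                           stopAccuracy = NULL, seed = 1, images = NULL) {
  if (is.null(images))
    images <- lapply(seq_len(nrow(manifest)), function(i)
      renderImage(dataset, manifest[i, ]))
  log <- data.frame(epoch = integer(), trainAcc = numeric(),
                    meanLoss = numeric())
  hits <- 0
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(manifest))
      nCorrect <- 0; loss <- 0
      for (i in ord) {
        pres <- applyAffine(images[[i]], sampleAffine(1, augment))
        input <- bpEncode(bp, pres)
        target <- numeric(length(bp@categories))
        target[match(manifest$category[i], bp@categories)] <- 1
        tr <- bpTrainTrial(bp, input, target)
        bp <- tr$bp
        nCorrect <- nCorrect + tr$correct
        loss <- loss + tr$loss
      }
      acc <- 100 * nCorrect / nrow(manifest)
      log <- rbind(log, data.frame(epoch = ep, trainAcc = acc,
                                   meanLoss = loss / nrow(manifest)))
      hits <- if (!is.null(stopAccuracy) && acc >= stopAccuracy) hits + 1 else 0
      if (hits >= 2) break
    }
  })
  list(bp = bp, log = log)
}
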