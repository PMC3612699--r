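#' Cosine similarity (normalized inner product)
#'
#' @param a,b Numeric vectors of equal length.
#' @return \code{sum(a * b) / (||a|| ||b||)}; defined as 0 when either
#'   vector is all-zero.
#' @examples
#' cosineSim(c(1, 1, 0), c(1, 0, 0))  # ~0.7071
#' @export
cosineSim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Per-cycle completion trajectory under occlusion
#'
#' Settles the network on an occluded presentation of an image while
#' recording snapshots, and reports for every layer and cycle the cosine of
#' the layer's activation to its final settled state on the unoccluded
#' presentation (same affine transform), i.e. the degree to which the
#' network reconstructs ("completes") the unoccluded representation.
#'
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @param img Normalized image matrix.
#' @param O Occlusion level in \code{[0,1]}.
#' @param filter A \code{\linkS4class{BlobFilter}} (built for the image size
#'   if missing).
#' @param occlusionSeed Seed for blob placement.
#' @param affineParams Affine transform shared by the occluded and the
#'   reference presentation (default identity).
#' @param reference Optional precomputed reference state (the settled
#'   per-layer activations for the unoccluded presentation).
#' @return Long-format data frame: \code{layer}, \code{cycle}, \code{cosine};
#'   \code{attr(, "cycles")} gives the settling length and
#'   \code{attr(, "reference")} the reference activations.
#' @export
completionTrajectory <- function(net, img, O, filter = NULL, occlusionSeed = 1,
                                 affineParams = identityAffine(),
                                 reference = NULL) {
  if (is.null(filter) && O > 0) filter <- buildBlobFilter(nrow(img))
  pres <- applyAffine(img, affineParams)
  if (is.null(reference)) {
    ref <- settle(net, v1Clamp(net, pres))
    reference <- lapply(ref$state, `[[`, "act")
  }
  occ <- if (O > 0) {
    occImg <- occludeImage(img, filter, O, seed = occlusionSeed)
    attr(occImg, "weightMap") <- NULL
    applyAffine(occImg, affineParams)
  } else pres
  run <- settle(net, v1Clamp(net, occ), record = TRUE)
  rows <- do.call(rbind, lapply(seq_along(run$snapshots), function(cy) {
    snap <- run$snapshots[[cy]]
    data.frame(layer = names(snap), cycle = cy,
               cosine = vapply(names(snap), function(nm)
                 cosineSim(snap[[nm]], reference[[nm]]), numeric(1)),
               row.names = NULL)
  }))
  attr(rows, "cycles") <- run$cycles
  attr(rows, "reference") <- reference
  rows
}

# single-presentation output activation for either model family
outputActivation <- function(model, img) {
  if (is(model, "KwtaNetwork")) {
    settle(model, v1Clamp(model, img))$state$Output$act
  } else if (is(model, "BpNetwork")) {
    acts <- bpForward(model, bpEncode(model, img))
    acts[[length(acts)]]
  } else stop("unsupported model class: ", class(model))
}

modelCategories <- function(model) model@categories

#' Majority-vote recognition of one image
#'
#' Presents the image \code{nPresentations} times (default 7), each with a
#' fresh random affine transform; any occlusion mask is applied once, before
#' the transforms, so the occluded features are identical across
#' presentations. The winner is the modal single-presentation category;
#' ties are broken by highest summed output activation, then lowest
#' category index.
#'
#' @param model A \code{\linkS4class{KwtaNetwork}} or
#'   \code{\linkS4class{BpNetwork}}.
#' @param img Normalized image matrix.
#' @param nPresentations Number of transformed presentations (>= 1).
#' @param O Occlusion level (0 = none).
#' @param filter Blob filter (defaults to one for this image size when
#'   \code{O > 0}).
#' @param augment Affine ranges for the presentations.
#' @param seed Integer seed (occlusion placement and transform draws).
#' @return List of class \code{VoteResult}: \code{votes} (per-presentation
#'   winners), \code{winner}, \code{activationSums} (summed output
#'   activation per category), \code{tie} (was a tie broken).
#' @export
voteRecognition <- function(model, img, nPresentations = 7, O = 0,
                            filter = NULL, augment = defaultAffineRanges(),
                            seed = 1) {
  stopifnot(nPresentations >= 1)
  cats <- modelCategories(model)
  withSeed(seed, {
    if (O > 0) {
      if (is.null(filter)) filter <- buildBlobFilter(nrow(img))
      img <- occludeImage(img, filter, O)
      attr(img, "weightMap") <- NULL
    }
    outs <- matrix(0, nPresentations, length(cats))
    for (i in seq_len(nPresentations)) {
      pres <- applyAffine(img, sampleAffine(1, augment))
      outs[i, ] <- outputActivation(model, pres)
    }
    votes <- cats[apply(outs, 1, whichMax1)]
    tallyWinner(votes, colSums(outs), cats)
  })
}

# modal category with the summed-activation, then lowest-index tie rule
tallyWinner <- function(votes, activationSums, cats) {
  counts <- table(factor(votes, levels = cats))
  top <- names(counts)[counts == max(counts)]
  tie <- length(top) > 1
  if (tie) {
    sums <- activationSums[match(top, cats)]
    top <- top[order(-sums, match(top, cats))]
  }
  structure(list(votes = votes, winner = top[1],
                 activationSums = setNames(activationSums, cats), tie = tie),
            class = "VoteResult")
}

#' Second-order majority vote across renders
#'
#' Takes the modal first-order winner over a list of
#' \code{\link{voteRecognition}} results (e.g. the renders of one exemplar),
#' with the same tie rule (summed activation, then lowest index).
#'
#' @param voteResults Nonempty list of \code{VoteResult}s.
#' @return The winning category label.
#' @export
secondOrderVote <- function(voteResults) {
  if (length(voteResults) == 0) stop("empty vote list")
  cats <- names(voteResults[[1]]$activationSums)
  winners <- vapply(voteResults, `[[`, character(1), "winner")
  sums <- Reduce(`+`, lapply(voteResults, `[[`, "activationSums"))
  tallyWinner(winners, sums, cats)$winner
}

#' Recognition accuracy over a test manifest
#'
#' Evaluates voted recognition for every image of the manifest, optionally
#' under occlusion. Vote modes: \code{"none"} (one random presentation,
#' single-trial argmax), \code{"vote2d"} (7-transform majority vote per
#' image), \code{"full"} (second-order majority over the renders of each
#' exemplar, on top of per-image 7-transform votes; accuracy is then per
#' exemplar).
#'
#' @param model A \code{\linkS4class{KwtaNetwork}} or
#'   \code{\linkS4class{BpNetwork}}.
#' @param dataset Dataset providing \code{renderImage}.
#' @param manifest Manifest rows to evaluate.
#' @param voteMode One of \code{"none"}, \code{"vote2d"}, \code{"full"}.
#' @param O Occlusion level.
#' @param nPresentations Presentations per image for the voting modes.
#' @param augment Affine ranges.
#' @param seed Integer seed.
#' @return Accuracy in percent, with \code{attr(, "perCategory")} the
#'   per-category percentages and \code{attr(, "n")} the number of scored
#'   items.
#' @export
evaluateAccuracy <- function(model, dataset, manifest,
                             voteMode = c("vote2d", "none", "full"), O = 0,
                             nPresentations = 7,
                             augment = defaultAffineRanges(), seed = 1) {
  voteMode <- match.arg(voteMode)
  if (nrow(manifest) == 0) stop("empty test set")
  filter <- if (O > 0) buildBlobFilter(dataset$spec$imageSize) else NULL
  nPres <- if (voteMode == "none") 1 else nPresentations
  rowVote <- function(i, s)
    voteRecognition(model, renderImage(dataset, manifest[i, ]), nPres, O = O,
                    filter = filter, augment = augment, seed = s)
  seeds <- mixSeed(seed, 1) + seq_len(nrow(manifest))
  if (voteMode %in% c("none", "vote2d")) {
    pred <- vapply(seq_len(nrow(manifest)),
                   function(i) rowVote(i, seeds[i])$winner, character(1))
    truth <- manifest$category
  } else {
    key <- paste(manifest$category, manifest$exemplar)
    groups <- split(seq_len(nrow(manifest)), key)
    pred <- vapply(groups, function(idx)
      secondOrderVote(lapply(idx, function(i) rowVote(i, seeds[i]))),
      character(1))
    truth <- vapply(groups, function(idx) manifest$category[idx[1]],
                    character(1))
  }
  acc <- 100 * mean(pred == truth)
  perCat <- 100 * tapply(pred == truth, truth, mean)
  structure(acc, perCategory = perCat, n = length(truth))
}

#' Occlusion sweep
#'
#' Evaluates accuracy at each occlusion level for each named model, the
#' protocol used for occlusion testing: per-image 7-transform voting with
#' the mask applied before the transforms.
#'
#' @param models Named list of models.
#' @param dataset,manifest Evaluation data.
#' @param levels Occlusion levels (default \code{c(0, 0.25, 0.5, 0.75)}).
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{evaluateAccuracy}}.
#' @return Data frame: \code{model}, \code{O}, \code{accuracy},
#'   \code{relative} (percent of the first model's accuracy at that level).
#' @export
occlusionSweep <- function(models, dataset, manifest,
                           levels = c(0, 0.25, 0.5, 0.75), seed = 1, ...) {
  out <- do.call(rbind, lapply(names(models), function(nm) {
    accs <- vapply(levels, function(O)
      as.numeric(evaluateAccuracy(models[[nm]], dataset, manifest,
                                  voteMode = "vote2d", O = O,
                                  seed = mixSeed(seed, match(nm, names(models))),
                                  ...)),
      numeric(1))
    data.frame(model = nm, O = levels, accuracy = accs)
  }))
  refAcc <- out$accuracy[out$model == names(models)[1]]
  out$relative <- 100 * out$accuracy / refAcc[match(out$O, levels)]
  out
}

#' Pearson correlation between two distance matrices
#'
#' Correlates the off-diagonal upper-triangle entries of two equally sized
#' similarity (or distance) matrices, the standard representational
#' similarity comparison.
#'
#' @param dm1,dm2 Square matrices of identical dimension (n >= 3).
#' @return Pearson correlation coefficient.
#' @export
dmCorrelation <- function(dm1, dm2) {
  if (!all(dim(dm1) == dim(dm2))) stop("matrices must have identical shape")
  if (nrow(dm1) < 3) stop("need at least 3 categories")
  off <- upper.tri(dm1)
  a <- dm1[off]; b <- dm2[off]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("distance matrix is constant; correlation undefined")
  cor(a, b)
}

#' Category-level representational distance matrix
#'
#' Mean settled activation per category at the named layer over the given
#' manifest rows, then the pairwise cosine similarity matrix of those
#' category means.
#'
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @param dataset,manifest Evaluation data (every category must appear).
#' @param layer Layer name (default "IT").
#' @return Symmetric cosine similarity matrix with unit diagonal, labelled
#'   by category.
#' @export
categoryDM <- function(net, dataset, manifest, layer = "IT") {
  cats <- net@categories
  missing <- setdiff(cats, unique(manifest$category))
  if (length(missing))
    stop("no test items for category: ", paste(missing, collapse = ", "))
  means <- vapply(cats, function(cat) {
    idx <- which(manifest$category == cat)
    acts <- vapply(idx, function(i) {
      img <- renderImage(dataset, manifest[i, ])
      settle(net, v1Clamp(net, img))$state[[layer]]$act
    }, numeric(layerSize(net, layer)))
    rowMeans(acts)
  }, numeric(layerSize(net, layer)))
  n <- length(cats)
  dm <- matrix(1, n, n, dimnames = list(cats, cats))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    dm[i, j] <- dm[j, i] <- cosineSim(means[, i], means[, j])
  dm
}

#' Semantic inference trajectory for one image
#'
#' Settles the network on the image with only V1 clamped (the semantics
#' layer free) and reports, per cycle, the cosine of the semantics-layer
#' activation to every category's canonical semantic pattern, the final
#' ranking, and a baseline (the mean final similarity across all
#' non-top-ranked categories). Used to probe what the network infers about
#' categories it was never trained on.
#'
#' @param net A \code{\linkS4class{KwtaNetwork}} with a Semantics layer.
#' @param img Normalized image matrix.
#' @param pset \code{\linkS4class{SemanticPatternSet}} with one pattern per
#'   network category (same order).
#' @return List: \code{trajectory} (data frame category, cycle, cosine),
#'   \code{final} (named final similarities, sorted), \code{ranking}
#'   (category labels best-first), \code{baseline}.
#' @export
semanticInference <- function(net, img, pset) {
  if (!"Semantics" %in% layerNames(net))
    stop("network has no Semantics layer")
  run <- settle(net, v1Clamp(net, img), record = TRUE)
  cats <- net@categories
  traj <- do.call(rbind, lapply(seq_along(run$snapshots), function(cy) {
    sem <- run$snapshots[[cy]]$Semantics
    data.frame(category = cats, cycle = cy,
               cosine = vapply(seq_along(cats), function(i)
                 cosineSim(sem, patternFor(pset, i)), numeric(1)),
               row.names = NULL)
  }))
  finalSem <- run$state$Semantics$act
  final <- sort(vapply(seq_along(cats), function(i)
    cosineSim(finalSem, patternFor(pset, i)), numeric(1)) |>
      setNames(cats), decreasing = TRUE)
  list(trajectory = traj, final = final, ranking = names(final),
       baseline = mean(final[-1]))
}
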