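#' Synthetic block-structured target similarity matrix
#'
#' Stands in for a corpus-derived (LSA-style) category similarity matrix:
#' within-cluster similarity exceeds between-cluster similarity, with
#' optional superordinate blocks grouping clusters hierarchically.
#' Symmetric with unit diagonal.
#'
#' @param nCategories Number of categories.
#' @param clusters Either a cluster count (categories split as evenly as
#'   possible) or an integer vector of cluster ids, one per category.
#' @param within,between Similarity within / between clusters.
#' @param superordinate Optional list: \code{groups} (cluster id -> group id)
#'   and \code{level} (similarity between clusters sharing a group).
#' @param noise SD of symmetric Gaussian jitter added off-diagonal (values
#'   clipped to \code{[0,1]}).
#' @param seed Integer seed for the jitter.
#' @return \code{nCategories x nCategories} similarity matrix with the
#'   cluster assignment in \code{attr(, "clusters")}.
#' @export
makeTargetDM <- function(nCategories, clusters, within = 0.6, between = 0.2,
                         superordinate = NULL, noise = 0, seed = 1) {
  if (length(clusters) == 1) {
    clusters <- rep(seq_len(clusters), length.out = nCategories)
    clusters <- sort(clusters)
  }
  if (length(clusters) != nCategories)
    stop("configuration error: cluster assignment must cover every category")
  dm <- matrix(between, nCategories, nCategories)
  same <- outer(clusters, clusters, "==")
  dm[same] <- within
  if (!is.null(superordinate)) {
    grp <- superordinate$groups[clusters]
    sameGrp <- outer(grp, grp, "==") & !same
    dm[sameGrp] <- superordinate$level
  }
  if (noise > 0) withSeed(seed, {
    jit <- matrix(rnorm(nCategories^2, 0, noise), nCategories)
    jit <- (jit + t(jit)) / 2
    dm <- matrix(pmin(1, pmax(0, dm + jit)), nCategories, nCategories)
  })
  diag(dm) <- 1
  attr(dm, "clusters") <- clusters
  dm
}

#' SemanticPatternSet: sparse binary category patterns
#'
#' One binary vector per category, each with exactly \code{nActive} on-bits
#' (a fixed activity fraction matching the kWTA dynamics of the semantics
#' layer). Patterns are shaped toward a target similarity matrix by
#' \code{\link{shapePatterns}}; \code{fitTrace} records the mismatch after
#' every accepted shaping move.
#'
#' @slot patterns n x u binary (0/1) matrix, one pattern per row.
#' @slot nActive On-bits per pattern.
#' @slot fitTrace Mismatch values at initialization and after each accepted
#'   move.
#' @slot stalled TRUE if shaping terminated on a stall (no accepted move
#'   within the stall budget).
#' @export
setClass("SemanticPatternSet",
  representation(patterns = "matrix", nActive = "integer",
                 fitTrace = "numeric", stalled = "logical"),
  validity = function(object) {
    p <- object@patterns
    if (!all(p %in% c(0, 1))) return("patterns must be binary")
    if (!all(rowSums(p) == object@nActive))
      return("every pattern must have exactly nActive on-bits")
    TRUE
  })

setMethod("show", "SemanticPatternSet", function(object) {
  cat("SemanticPatternSet:", nrow(object@patterns), "patterns x",
      ncol(object@patterns), "units,", object@nActive, "bits active (",
      round(100 * object@nActive / ncol(object@patterns), 1), "% );",
      length(object@fitTrace) - 1, "accepted shaping moves\n")
})

#' @rdname initPatterns
#' @param pset A \code{\linkS4class{SemanticPatternSet}}.
#' @param i Pattern (category) index.
#' @export
patternFor <- function(pset, i) as.numeric(pset@patterns[i, ])

#' Initialize random sparse binary patterns
#'
#' @param n Number of patterns (categories).
#' @param u Units per pattern (default 100).
#' @param pctActive Active fraction (default 0.25; \code{round(pctActive * u)}
#'   bits are on in every pattern).
#' @param seed Integer seed.
#' @return A \code{\linkS4class{SemanticPatternSet}} of distinct patterns.
#' @export
initPatterns <- function(n, u = 100, pctActive = 0.25, seed = 1) {
  a <- round(pctActive * u)
  if (a < 1) stop("pctActive too small: no bits active")
  if (a >= u && n > 1)
    stop("distinct patterns impossible: all units active")
  if (lchoose(u, a) < log(n))
    stop("distinct patterns impossible: n exceeds choose(u, a)")
  withSeed(seed, {
    pats <- matrix(0L, n, u)
    for (i in seq_len(n)) {
      repeat {
        v <- integer(u); v[sample.int(u, a)] <- 1L
        dup <- i > 1 && any(apply(pats[seq_len(i - 1), , drop = FALSE], 1,
                                  identical, y = v))
        if (!dup) { pats[i, ] <- v; break }
      }
    }
    new("SemanticPatternSet", patterns = pats, nActive = as.integer(a),
        fitTrace = numeric(0), stalled = FALSE)
  })
}

#' Pairwise cosine similarity matrix of a pattern set
#'
#' For equal-activity binary patterns the cosine equals on-bit overlap
#' divided by the activity count.
#'
#' @param pset A \code{\linkS4class{SemanticPatternSet}} (or binary matrix).
#' @return n x n cosine similarity matrix.
#' @export
patternDM <- function(pset) {
  p <- if (is(pset, "SemanticPatternSet")) pset@patterns else pset
  if (length(p) == 0) stop("empty pattern set")
  nrm <- sqrt(rowSums(p^2))
  dm <- tcrossprod(p) / outer(nrm, nrm)
  dm[!is.finite(dm)] <- 0
  dm
}

# mean absolute off-diagonal difference between two similarity matrices
dmMismatch <- function(dm1, dm2) {
  off <- upper.tri(dm1)
  mean(abs(dm1[off] - dm2[off]))
}

softmaxSample <- function(score, temperature) {
  w <- exp((score - max(score)) / temperature)
  sample.int(length(score), 1, prob = w)
}

#' Shape patterns toward a target similarity matrix
#'
#' Iterative ratcheting: each iteration picks a pattern (round-robin) and a
#' partner pattern, proposes turning ON one currently-off bit (chosen by a
#' softmax over bits weighted by the sum over other patterns of the target
#' similarity times that pattern's bits) and turning OFF one currently-on
#' bit (the complementary weighting, one minus the similarity), flipping the
#' pair so activity is preserved. The move is kept only if the mean absolute
#' difference between the patterns' off-diagonal cosine matrix and the
#' target strictly decreases. The fit trace is therefore strictly monotone
#' decreasing over accepted moves.
#'
#' @param pset A \code{\linkS4class{SemanticPatternSet}}.
#' @param target Target similarity matrix (n x n).
#' @param maxIters Number of proposed flips (default 2000).
#' @param temperature Softmax temperature for bit proposals (default 1).
#' @param stallLimit Consecutive rejected proposals after which shaping
#'   stops with \code{stalled = TRUE} (default 1000).
#' @param seed Integer seed.
#' @return The shaped \code{\linkS4class{SemanticPatternSet}} with its
#'   \code{fitTrace}.
#' @export
shapePatterns <- function(pset, target, maxIters = 2000, temperature = 1,
                          stallLimit = 1000, seed = 1) {
  p <- pset@patterns
  n <- nrow(p)
  if (nrow(target) != n) stop("target dimension must match pattern count")
  a <- pset@nActive
  dm <- patternDM(p)
  mismatch <- dmMismatch(dm, target)
  trace <- mismatch
  nOff <- n * (n - 1) / 2
  stallRun <- 0
  withSeed(seed, {
    for (it in seq_len(maxIters)) {
      i <- ((it - 1) %% n) + 1
      others <- seq_len(n)[-i]
      sim <- target[i, -i]
      offBits <- which(p[i, ] == 0)
      onBits <- which(p[i, ] == 1)
      scoreOn <- as.numeric(sim %*% p[others, offBits, drop = FALSE])
      scoreOff <- as.numeric((1 - sim) %*% p[others, onBits, drop = FALSE])
      bOn <- offBits[softmaxSample(scoreOn, temperature)]
      bOff <- onBits[softmaxSample(scoreOff, temperature)]
      newRow <- p[i, ]
      newRow[bOn] <- 1L; newRow[bOff] <- 0L
      newCos <- as.numeric(p[others, , drop = FALSE] %*% newRow) / a
      # incremental mismatch: only row/column i changes
      newMis <- mismatch + (sum(abs(newCos - sim)) -
                              sum(abs(dm[i, -i] - sim))) / nOff
      if (newMis < mismatch - 1e-12) {
        p[i, ] <- newRow
        dm[i, -i] <- newCos; dm[-i, i] <- newCos
        mismatch <- newMis
        trace <- c(trace, mismatch)
        stallRun <- 0
      } else {
        stallRun <- stallRun + 1
        if (stallRun >= stallLimit) { pset@stalled <- TRUE; break }
      }
    }
  })
  pset@patterns <- p
  pset@fitTrace <- trace
  validObject(pset)
  pset
}

#' Write / read a pattern set as CSV
#' @param pset A \code{\linkS4class{SemanticPatternSet}}.
#' @param path File path.
#' @return \code{readPatterns} returns a \code{SemanticPatternSet}.
#' @export
writePatterns <- function(pset, path) {
  write.csv(pset@patterns, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePatterns
#' @export
readPatterns <- function(path) {
  p <- as.matrix(read.csv(path))
  dimnames(p) <- NULL
  new("SemanticPatternSet", patterns = p, nActive = as.integer(sum(p[1, ])),
      fitTrace = numeric(0), stalled = FALSE)
}
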