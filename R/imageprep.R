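#' Normalize a raster image to the model's working format
#'
#' Converts a raster (gray matrix, RGB array, or \pkg{EBImage} Image) to a
#' square grayscale matrix with values in \code{[0,1]}, resampled to
#' \code{targetSize} with neighborhood-smoothing (antialiased bilinear)
#' interpolation. This is the canonical input format for the whole pipeline;
#' the default working size is 144 pixels.
#'
#' @param raw A numeric matrix (grayscale), a 3-d numeric array with the
#'   third dimension indexing color channels, or an \code{EBImage::Image}.
#'   Values are expected in \code{[0,1]}; inputs in \code{[0,255]} are
#'   rescaled.
#' @param targetSize Side length in pixels of the square output (>= 8).
#' @return A \code{targetSize x targetSize} numeric matrix in \code{[0,1]}.
#' @examples
#' img <- normalizeImage(matrix(runif(100 * 80), 100, 80), targetSize = 32)
#' dim(img)
#' @export
normalizeImage <- function(raw, targetSize = 144) {
  if (is(raw, "Image")) raw <- EBImage::imageData(raw)
  if (length(raw) == 0) stop("invalid input: empty image")
  if (!is.numeric(raw)) stop("invalid input: image must be numeric")
  if (any(!is.finite(raw))) stop("invalid input: non-finite pixel values")
  if (targetSize < 8) stop("targetSize must be >= 8")
  if (length(dim(raw)) == 3) raw <- apply(raw, c(1, 2), mean)
  if (length(dim(raw)) != 2) stop("invalid input: expected 2-d or 3-d raster")
  if (max(raw) > 1) raw <- raw / 255
  out <- EBImage::resize(EBImage::Image(raw), w = targetSize, h = targetSize,
                         filter = "bilinear", antialias = TRUE)
  out <- EBImage::imageData(out)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Default affine augmentation ranges
#'
#' Uniform sampling ranges for the 2-d augmentation applied at every image
#' presentation: scale 0.9--1.1, translation -0.15--0.15 of the image size in
#' each axis, and rotation -0.02--0.02 of a full turn (1.0 = 360 degrees),
#' i.e. about 14 degrees total in-plane rotation range.
#'
#' @return A named list of length-2 numeric ranges
#'   (\code{scale}, \code{tx}, \code{ty}, \code{rot}).
#' @export
defaultAffineRanges <- function() {
  list(scale = c(0.9, 1.1), tx = c(-0.15, 0.15),
       ty = c(-0.15, 0.15), rot = c(-0.02, 0.02))
}

#' Identity affine ranges (degenerate: no augmentation)
#' @return Ranges that always sample the identity transform.
#' @export
identityAffineRanges <- function() {
  list(scale = c(1, 1), tx = c(0, 0), ty = c(0, 0), rot = c(0, 0))
}

#' Sample random affine parameters
#'
#' Draws \code{n} parameter sets, each independently uniform within its
#' configured range. Rotation uses the normalized convention 1.0 = 360
#' degrees; translation is a fraction of the image size.
#'
#' @param n Number of draws.
#' @param ranges Named list of ranges as from \code{\link{defaultAffineRanges}}.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Data frame with columns \code{scale}, \code{tx}, \code{ty},
#'   \code{rot}, one row per draw.
#' @export
sampleAffine <- function(n = 1, ranges = defaultAffineRanges(), seed = NULL) {
  for (nm in c("scale", "tx", "ty", "rot")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2])
      stop("configuration error: range '", nm, "' must be c(lo, hi) with lo <= hi")
  }
  withSeed(seed, data.frame(
    scale = runif(n, ranges$scale[1], ranges$scale[2]),
    tx    = runif(n, ranges$tx[1], ranges$tx[2]),
    ty    = runif(n, ranges$ty[1], ranges$ty[2]),
    rot   = runif(n, ranges$rot[1], ranges$rot[2])))
}

identityAffine <- function() data.frame(scale = 1, tx = 0, ty = 0, rot = 0)

#' Apply an affine transform to a normalized image
#'
#' Applies a single composed transform (scale, then rotate, then translate,
#' about the image center) with bilinear interpolation. Out-of-frame regions
#' are filled with the background gray. Identity parameters reproduce the
#' input bit-exactly.
#'
#' @param img Normalized image matrix in \code{[0,1]}.
#' @param p One-row data frame (or list) with \code{scale}, \code{tx},
#'   \code{ty}, \code{rot} as produced by \code{\link{sampleAffine}}.
#' @param background Fill gray level for out-of-frame pixels (default 0.5,
#'   matching the occluder's background).
#' @return Transformed image matrix, same size as the input.
#' @export
applyAffine <- function(img, p, background = 0.5) {
  stopifnot(is.matrix(img))
  p <- as.list(p)
  if (p$scale == 1 && p$tx == 0 && p$ty == 0 && p$rot == 0) return(img)
  w <- nrow(img); h <- ncol(img)
  theta <- p$rot * 2 * pi
  # forward map: out = (pt - c) %*% t(S R) + c + t   (row-vector convention)
  M <- p$scale * rbind(c(cos(theta), sin(theta)),
                       c(-sin(theta), cos(theta)))
  A <- t(M)
  cen <- c((w + 1) / 2, (h + 1) / 2)
  off <- cen - as.numeric(cen %*% A) + c(p$tx * w, p$ty * h)
  m <- rbind(A, off)
  out <- EBImage::affine(EBImage::Image(img), m, filter = "bilinear",
                         bg.col = background)
  out <- EBImage::imageData(out)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Specify a synthetic shape dataset
#'
#' Describes a generator that emulates the category / exemplar / render
#' structure of a rendered 3-d object dataset: each category has a base shape
#' (a seeded composite of 2--4 parametric primitives), each exemplar jitters
#' the base geometry, and each render jitters pose and adds a lighting
#' gradient. Exemplar variation exceeds render variation so that category
#' membership is only imperfectly recoverable from raw pixels.
#'
#' @param nCategories,exemplarsPerCategory,rendersPerExemplar Counts (>= 1);
#'   \code{exemplarsPerCategory} may be a vector of per-category counts
#'   (length \code{nCategories}), e.g. to emulate a corpus with an uneven
#'   average of exemplars per category.
#' @param imageSize Side length in pixels of generated images.
#' @param exemplarJitter Relative magnitude of per-exemplar geometry jitter.
#' @param renderJitter Relative magnitude of per-render pose/lighting jitter
#'   (statistically emulating modest in-depth rotation and overhead-arc
#'   lighting variability).
#' @param seed Integer master seed; everything downstream is derived from it.
#' @return An object of class \code{SyntheticDatasetSpec} (a list).
#' @export
syntheticDatasetSpec <- function(nCategories = 10, exemplarsPerCategory = 4,
                                 rendersPerExemplar = 5, imageSize = 64,
                                 exemplarJitter = 0.12, renderJitter = 0.05,
                                 seed = 1) {
  stopifnot(nCategories >= 1, all(exemplarsPerCategory >= 1),
            length(exemplarsPerCategory) %in% c(1, nCategories),
            rendersPerExemplar >= 1, imageSize >= 8,
            exemplarJitter >= 0, renderJitter >= 0)
  structure(list(nCategories = nCategories,
                 exemplarsPerCategory = exemplarsPerCategory,
                 rendersPerExemplar = rendersPerExemplar,
                 imageSize = imageSize,
                 exemplarJitter = exemplarJitter,
                 renderJitter = renderJitter,
                 seed = as.integer(seed)),
            class = "SyntheticDatasetSpec")
}

#' Generate a synthetic dataset manifest
#'
#' Builds the manifest (category, exemplar, render, per-image seed) for the
#' synthetic shape dataset described by \code{spec}. Images themselves are
#' rendered lazily by \code{\link{renderImage}}, so manifests of any size are
#' cheap to create. Fully deterministic given the spec's seed.
#'
#' @param spec A \code{\link{syntheticDatasetSpec}}.
#' @return A list with elements \code{manifest} (data frame with columns
#'   \code{category}, \code{exemplar}, \code{render}, \code{seed}),
#'   \code{categories} (category labels) and \code{spec}.
#' @examples
#' ds <- makeSyntheticDataset(syntheticDatasetSpec(3, 2, 2, imageSize = 24))
#' nrow(ds$manifest)  # 3 * 2 * 2
#' @export
makeSyntheticDataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticDatasetSpec"))
  cats <- sprintf("cat%03d", seq_len(spec$nCategories))
  nEx <- rep(spec$exemplarsPerCategory, length.out = spec$nCategories)
  manifest <- do.call(rbind, lapply(seq_len(spec$nCategories), function(ci)
    expand.grid(category = cats[ci], exemplar = seq_len(nEx[ci]),
                render = seq_len(spec$rendersPerExemplar),
                stringsAsFactors = FALSE)))
  manifest <- manifest[order(match(manifest$category, cats),
                             manifest$exemplar, manifest$render), ]
  manifest$seed <- mapply(function(ci, e, r) mixSeed(spec$seed, ci, e, r),
                          match(manifest$category, cats),
                          manifest$exemplar, manifest$render)
  rownames(manifest) <- NULL
  list(manifest = manifest, categories = cats, spec = spec)
}

# -- shape grammar -----------------------------------------------------------

# Soft-edged primitive masks over a pixel grid; smooth (sigmoidal) edges avoid
# aliasing artifacts under affine resampling. All coordinates are in [0,1]
# units of the image side.
primitiveMask <- function(type, par, X, Y, soft) {
  dx <- X - par$cx; dy <- Y - par$cy
  a <- par$rot
  xr <- cos(a) * dx + sin(a) * dy
  yr <- -sin(a) * dx + cos(a) * dy
  d <- switch(type,
    disk = sqrt(xr^2 + (yr / par$aspect)^2) - par$r,
    ring = abs(sqrt(xr^2 + (yr / par$aspect)^2) - par$r) - par$thick,
    bar  = pmax(abs(xr) - par$len, abs(yr) - par$thick),
    wedge = pmax(abs(xr) + yr * par$aspect - par$r, -yr - par$r))
  plogis(-d / soft)
}

samplePrimitive <- function() {
  type <- sample(c("disk", "ring", "bar", "wedge"), 1)
  list(type = type,
       par = list(cx = runif(1, 0.3, 0.7), cy = runif(1, 0.3, 0.7),
                  r = runif(1, 0.08, 0.22), thick = runif(1, 0.03, 0.08),
                  len = runif(1, 0.12, 0.3), aspect = runif(1, 0.7, 1.4),
                  rot = runif(1, 0, pi)),
       value = sample(c(runif(1, 0.0, 0.25), runif(1, 0.75, 1.0)), 1))
}

jitterPrimitive <- function(prim, mag) {
  p <- prim$par
  p$cx <- p$cx + rnorm(1, 0, mag * 0.25)
  p$cy <- p$cy + rnorm(1, 0, mag * 0.25)
  p$r <- max(0.03, p$r * exp(rnorm(1, 0, mag)))
  p$thick <- max(0.02, p$thick * exp(rnorm(1, 0, mag)))
  p$len <- max(0.05, p$len * exp(rnorm(1, 0, mag)))
  p$rot <- p$rot + rnorm(1, 0, mag * pi / 2)
  prim$par <- p
  prim$value <- min(1, max(0, prim$value + rnorm(1, 0, mag * 0.3)))
  prim
}

categoryBaseShape <- function(spec, categoryIndex) {
  withSeed(mixSeed(spec$seed, categoryIndex, 0, 0), {
    nPrim <- sample(2:4, 1)
    lapply(seq_len(nPrim), function(i) samplePrimitive())
  })
}

exemplarShape <- function(spec, categoryIndex, exemplar) {
  base <- categoryBaseShape(spec, categoryIndex)
  withSeed(mixSeed(spec$seed, categoryIndex, exemplar, 0),
           lapply(base, jitterPrimitive, mag = spec$exemplarJitter))
}

#' Render one image of a synthetic dataset
#'
#' Deterministically renders the image for a manifest row: the category base
#' shape, with the exemplar's geometry jitter, the render's pose jitter and a
#' render-specific brightness (lighting) gradient, drawn on a uniform 0.5
#' gray background.
#'
#' @param dataset A dataset as returned by \code{\link{makeSyntheticDataset}}.
#' @param row Either a row index into \code{dataset$manifest} or a one-row
#'   manifest data frame.
#' @return A normalized image matrix in \code{[0,1]}.
#' @export
renderImage <- function(dataset, row) {
  spec <- dataset$spec
  if (is.numeric(row)) row <- dataset$manifest[row, ]
  ci <- match(row$category, dataset$categories)
  if (is.na(ci)) stop("unknown category: ", row$category)
  prims <- exemplarShape(spec, ci, row$exemplar)
  n <- spec$imageSize
  ax <- (seq_len(n) - 0.5) / n
  X <- matrix(ax, n, n); Y <- matrix(ax, n, n, byrow = TRUE)
  soft <- 1.5 / n
  withSeed(mixSeed(spec$seed, ci, row$exemplar, row$render, 7), {
    img <- matrix(0.5, n, n)
    rj <- spec$renderJitter
    pose <- list(scale = exp(rnorm(1, 0, rj * 0.5)),
                 tx = rnorm(1, 0, rj * 0.3), ty = rnorm(1, 0, rj * 0.3),
                 rot = rnorm(1, 0, rj * 0.5))
    for (prim in prims) {
      p <- prim$par
      dx <- p$cx - 0.5; dy <- p$cy - 0.5
      p$cx <- 0.5 + pose$scale * (cos(pose$rot) * dx + sin(pose$rot) * dy) + pose$tx
      p$cy <- 0.5 + pose$scale * (-sin(pose$rot) * dx + cos(pose$rot) * dy) + pose$ty
      p$r <- p$r * pose$scale; p$len <- p$len * pose$scale
      p$rot <- p$rot + pose$rot
      m <- primitiveMask(prim$type, p, X, Y, soft)
      img <- img * (1 - m) + prim$value * m
    }
    # lighting: multiplicative brightness gradient from a random overhead angle
    ang <- runif(1, -pi / 4, pi / 4)
    grad <- 1 + 4 * rj * ((X - 0.5) * sin(ang) + (0.5 - Y) * cos(ang))
    img <- 0.5 + (img - 0.5) * grad
    img[img < 0] <- 0; img[img > 1] <- 1
    img
  })
}

#' Split a manifest into train and test sets by exemplar
#'
#' Reserves \code{nTestExemplars} whole exemplars per category for testing
#' (all renders of a held-out exemplar go to the test set), so that test
#' items are genuinely novel objects.
#'
#' @param manifest Manifest data frame with columns \code{category},
#'   \code{exemplar}, \code{render}.
#' @param nTestExemplars Exemplars reserved per category (default 2).
#' @param seed Integer seed for the random choice of held-out exemplars.
#' @return List with \code{train} and \code{test} manifest data frames.
#' @export
splitTrainTest <- function(manifest, nTestExemplars = 2, seed = 1) {
  stopifnot(nTestExemplars >= 0)
  if (nTestExemplars == 0)
    return(list(train = manifest, test = manifest[0, ]))
  testRows <- logical(nrow(manifest))
  withSeed(seed, for (cat in unique(manifest$category)) {
    ex <- unique(manifest$exemplar[manifest$category == cat])
    if (length(ex) <= nTestExemplars)
      stop("category '", cat, "' has only ", length(ex),
           " exemplars; cannot reserve ", nTestExemplars, " for testing")
    held <- sample(ex, nTestExemplars)
    testRows <- testRows | (manifest$category == cat & manifest$exemplar %in% held)
  })
  list(train = manifest[!testRows, , drop = FALSE],
       test = manifest[testRows, , drop = FALSE])
}

#' Write / read a manifest as CSV
#' @param manifest Manifest data frame.
#' @param path File path.
#' @return \code{readManifest} returns the manifest data frame.
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) read.csv(path, stringsAsFactors = FALSE)
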