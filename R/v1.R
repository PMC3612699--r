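#' @include utils.R
NULL

#' FilterBank: oriented Gabor quadrature filter bank
#'
#' A fixed filtering front-end standing in for retina-to-V1 processing:
#' even/odd (quadrature-phase) Gabor pairs at several orientations and
#' spatial scales model V1 simple cells; local max-pooling over position and
#' phase models complex cells. All filters are zero-mean with unit L2 norm.
#'
#' @slot filters List over scales, each a list over orientations of
#'   \code{list(even, odd)} filter matrices.
#' @slot orientations Orientations in radians.
#' @slot nScales Number of dyadic scales (scale s sees the image box-downsampled
#'   by \code{2^(s-1)}).
#' @slot filterSize Side length of the square filters (odd).
#' @slot poolSize Complex-cell pooling neighborhood (\code{poolSize x
#'   poolSize} blocks sampled every \code{poolStride} pixels; overlapping
#'   when \code{poolStride < poolSize}).
#' @slot poolStride Pooling grid stride in pixels.
#' @slot responseNorm Per-orientation normalizing constants (response of the
#'   filter pair to a full-contrast step edge at its preferred orientation),
#'   fixed at construction so encoding is not image-adaptive.
#' @export
setClass("FilterBank",
  representation(filters = "list", orientations = "numeric",
                 nScales = "integer", filterSize = "integer",
                 poolSize = "integer", poolStride = "integer",
                 responseNorm = "numeric"),
  validity = function(object) {
    msg <- character()
    for (sc in object@filters) for (f in sc) {
      if (abs(mean(f$even)) > 1e-8 || abs(mean(f$odd)) > 1e-8)
        msg <- c(msg, "filters must be zero-mean")
      if (abs(sqrt(sum(f$even^2)) - 1) > 1e-8 ||
          abs(sqrt(sum(f$odd^2)) - 1) > 1e-8)
        msg <- c(msg, "filters must have unit L2 norm")
    }
    if (length(msg)) unique(msg) else TRUE
  })

setMethod("show", "FilterBank", function(object) {
  cat("FilterBank:", length(object@orientations), "orientations x",
      object@nScales, "scales,", object@filterSize, "px filters,",
      object@poolSize, "x", object@poolSize, "complex-cell pooling\n")
})

gaborFilter <- function(size, theta, wavelength, sigma, phase, aspect = 0.8) {
  half <- (size - 1) / 2
  ax <- seq(-half, half)
  X <- matrix(ax, size, size); Y <- matrix(ax, size, size, byrow = TRUE)
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  g <- exp(-(xr^2 + (aspect * yr)^2) / (2 * sigma^2)) *
    cos(2 * pi * xr / wavelength + phase)
  g <- g - mean(g)
  g / sqrt(sum(g^2))
}

#' Build a Gabor quadrature filter bank
#'
#' @param nOrientations Number of evenly spaced orientations (>= 2; default 4:
#'   0, 45, 90, 135 degrees).
#' @param nScales Number of dyadic scales (default 2).
#' @param filterSize Filter side length in pixels (odd; default 7).
#' @param wavelength Carrier wavelength in pixels (default \code{filterSize - 1}).
#' @param sigma Gaussian envelope SD in pixels (default \code{0.4 * wavelength}).
#' @param poolSize Complex-cell pooling block (default 2).
#' @param poolStride Pooling grid stride (default \code{poolSize}, i.e.
#'   non-overlapping; smaller values give overlapping complex-cell
#'   receptive fields, trading more units for translation tolerance at
#'   retained resolution).
#' @return A \code{\linkS4class{FilterBank}}.
#' @examples
#' bank <- buildFilterBank()
#' bank
#' @export
buildFilterBank <- function(nOrientations = 4, nScales = 2, filterSize = 7,
                            wavelength = filterSize - 1,
                            sigma = 0.4 * wavelength, poolSize = 2,
                            poolStride = poolSize) {
  if (nOrientations < 2) stop("configuration error: nOrientations must be >= 2")
  if (filterSize %% 2 == 0)
    stop("configuration error: filterSize must be odd for centered quadrature pairs")
  thetas <- pi * (seq_len(nOrientations) - 1) / nOrientations
  mk <- function() lapply(thetas, function(th)
    list(even = gaborFilter(filterSize, th, wavelength, sigma, 0),
         odd = gaborFilter(filterSize, th, wavelength, sigma, pi / 2)))
  filters <- lapply(seq_len(nScales), function(s) mk())
  bank <- new("FilterBank", filters = filters, orientations = thetas,
              nScales = as.integer(nScales), filterSize = as.integer(filterSize),
              poolSize = as.integer(poolSize),
              poolStride = as.integer(poolStride),
              responseNorm = rep(1, nOrientations))
  # normalization: peak pooled response to a full-contrast preferred-orientation
  # step edge, computed once here so encoding stays contrast-monotone
  sz <- max(4 * filterSize, 16)
  norms <- vapply(seq_along(thetas), function(oi) {
    edge <- stepEdgeImage(sz, thetas[oi])
    r <- simpleCellResponses(edge, bank@filters[[1]][[oi]])
    max(pmax(abs(r$even), abs(r$odd)))
  }, numeric(1))
  bank@responseNorm <- norms
  bank
}

stepEdgeImage <- function(size, theta) {
  ax <- seq_len(size) - (size + 1) / 2
  X <- matrix(ax, size, size); Y <- matrix(ax, size, size, byrow = TRUE)
  # edge perpendicular to the filter's carrier direction
  (sign(X * cos(theta) + Y * sin(theta)) + 1) / 2
}

simpleCellResponses <- function(img, pair) {
  list(even = conv2circ(img, pair$even), odd = conv2circ(img, pair$odd))
}

# circular ("same") 2-d correlation, equivalent to EBImage::filter2 but via a
# cached neighbor-index gather and one matrix product per call -- much faster
# for small kernels applied many times
.convCache <- new.env(parent = emptyenv())

convIndex <- function(nx, ny, fs) {
  key <- paste(nx, ny, fs, sep = "x")
  if (!is.null(.convCache[[key]])) return(.convCache[[key]])
  half <- (fs - 1) / 2
  off <- seq(-half, half)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  px <- wrap(outer(seq_len(nx), off, "+"), nx)          # nx x fs
  py <- wrap(outer(seq_len(ny), off, "+"), ny)          # ny x fs
  # linear indices of each pixel's fs x fs neighborhood, neighborhood fastest
  pix <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  idx <- matrix(0L, nx * ny, fs * fs)
  col <- 0L
  for (b in seq_len(fs)) for (a in seq_len(fs)) {
    col <- col + 1L
    idx[, col] <- px[pix$x, a] + (py[pix$y, b] - 1L) * nx
  }
  .convCache[[key]] <- idx
  idx
}

conv2circ <- function(img, kernel) {
  fs <- nrow(kernel)
  idx <- convIndex(nrow(img), ncol(img), fs)
  flipped <- kernel[fs:1, fs:1]          # convolution, as filter2 does
  matrix(matrix(img[idx], nrow(idx)) %*% as.numeric(flipped),
         nrow(img), ncol(img))
}

boxDownsample <- function(img, factor = 2) {
  n <- floor(dim(img) / factor) * factor
  img <- img[seq_len(n[1]), seq_len(n[2]), drop = FALSE]
  nx <- n[1] / factor; ny <- n[2] / factor
  out <- matrix(0, nx, ny)
  for (i in seq_len(factor)) for (j in seq_len(factor))
    out <- out + img[seq(i, n[1], by = factor), seq(j, n[2], by = factor)]
  out / factor^2
}

maxPool <- function(m, pool, stride = pool) {
  nx <- floor((nrow(m) - pool) / stride) + 1
  ny <- floor((ncol(m) - pool) / stride) + 1
  out <- matrix(-Inf, nx, ny)
  for (i in seq_len(pool)) for (j in seq_len(pool))
    out <- pmax(out, m[seq(i, by = stride, length.out = nx),
                       seq(j, by = stride, length.out = ny)])
  out
}

#' V1Activation: sparse oriented-edge encoding of one image
#'
#' @slot act List over scales of 3-d arrays \code{[x, y, orientation]} of
#'   complex-cell activations in \code{[0,1]}.
#' @slot raw Same structure, pre-kWTA (dense) responses.
#' @slot activeFraction Fraction of units active after sparsification.
#' @slot kwtaPct The sparsity bound that was applied (NA if none).
#' @export
setClass("V1Activation",
  representation(act = "list", raw = "list", activeFraction = "numeric",
                 kwtaPct = "numeric"),
  validity = function(object) {
    for (a in object@act)
      if (min(a) < 0 || max(a) > 1) return("activations must lie in [0,1]")
    if (!is.na(object@kwtaPct) &&
        object@activeFraction > object@kwtaPct + 1e-12)
      return("active fraction exceeds the kWTA bound")
    TRUE
  })

setMethod("show", "V1Activation", function(object) {
  cat("V1Activation:", length(v1Vector(object)), "units,",
      round(100 * object@activeFraction, 1), "% active\n")
})

#' Flatten a V1 activation to the network input vector
#' @param v A \code{\linkS4class{V1Activation}}.
#' @param raw Use the dense pre-kWTA responses instead of the sparse code.
#' @return Numeric vector (fixed unit order across images of equal geometry).
#' @export
v1Vector <- function(v, raw = FALSE) {
  unlist(lapply(if (raw) v@raw else v@act, as.numeric), use.names = FALSE)
}

# hard k-winners-take-all on a value vector: keep the k largest, zero the rest;
# ties at the boundary resolved by stable index order
hardKwta <- function(x, k) {
  if (k >= length(x)) return(x)
  if (k <= 0) return(rep(0, length(x)))
  keep <- head(order(x, seq_along(x), decreasing = TRUE), k)
  out <- numeric(length(x))
  out[keep] <- x[keep]
  out
}

#' Encode an image through the V1 front-end
#'
#' Convolves the image with the bank's even/odd pairs (simple cells), takes
#' the max over phase and a local \code{poolSize} max-pool (complex cells),
#' normalizes by the fixed per-orientation edge response, clips to
#' \code{[0,1]}, and applies k-winners-take-all sparsification per scale so
#' at most \code{kwtaPct} of units are active.
#'
#' @param img Normalized image matrix.
#' @param bank A \code{\linkS4class{FilterBank}}.
#' @param kwtaPct Maximum active fraction (default 0.2, within the 15--25\%
#'   neocortical range); \code{NA} disables sparsification.
#' @return A \code{\linkS4class{V1Activation}}.
#' @export
v1Encode <- function(img, bank, kwtaPct = 0.2) {
  stopifnot(is.matrix(img))
  nOri <- length(bank@orientations)
  raw <- vector("list", bank@nScales)
  cur <- img
  for (s in seq_len(bank@nScales)) {
    if (s > 1) cur <- boxDownsample(cur, 2)
    pooledDim <- floor((dim(cur) - bank@poolSize) / bank@poolStride) + 1
    arr <- array(0, c(pooledDim, nOri))
    # one neighborhood gather + one matrix product for all quadrature pairs
    fs <- bank@filterSize
    kmat <- vapply(bank@filters[[s]], function(pr)
      cbind(as.numeric(pr$even[fs:1, fs:1]), as.numeric(pr$odd[fs:1, fs:1])),
      matrix(0, fs * fs, 2))
    dim(kmat) <- c(fs * fs, 2 * nOri)
    patches <- matrix(cur[convIndex(nrow(cur), ncol(cur), fs)], nrow(cur) * ncol(cur))
    resp <- patches %*% kmat
    for (oi in seq_len(nOri)) {
      even <- matrix(resp[, 2 * oi - 1], nrow(cur))
      odd <- matrix(resp[, 2 * oi], nrow(cur))
      complexResp <- pmax(abs(even), abs(odd)) / bank@responseNorm[oi]
      complexResp[complexResp > 1] <- 1
      complexResp[complexResp < 1e-9] <- 0   # numerical residue on flat regions
      arr[, , oi] <- maxPool(complexResp, bank@poolSize, bank@poolStride)
    }
    raw[[s]] <- arr
  }
  act <- raw
  if (!is.na(kwtaPct)) {
    for (s in seq_along(act)) {
      k <- floor(kwtaPct * length(act[[s]]))
      act[[s]] <- array(hardKwta(as.numeric(act[[s]]), k), dim(act[[s]]))
    }
  }
  total <- sum(vapply(act, length, numeric(1)))
  new("V1Activation", act = act, raw = raw,
      activeFraction = sum(vapply(act, function(a) sum(a > 0), numeric(1))) / total,
      kwtaPct = if (is.na(kwtaPct)) NA_real_ else kwtaPct)
}

#' Number of units the bank produces for a given image size
#' @param bank A \code{\linkS4class{FilterBank}}.
#' @param imageSize Image side length in pixels.
#' @return Integer unit count of the flattened V1 vector.
#' @export
v1Size <- function(bank, imageSize) {
  n <- 0; sz <- c(imageSize, imageSize)
  for (s in seq_len(bank@nScales)) {
    if (s > 1) sz <- floor(sz / 2)
    pooled <- floor((sz - bank@poolSize) / bank@poolStride) + 1
    n <- n + prod(pooled) * length(bank@orientations)
  }
  as.integer(n)
}
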