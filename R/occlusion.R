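#' BlobFilter: Gaussian-edged circular occlusion mask
#'
#' A radial weighting function used to occlude image regions toward the
#' background gray: weight 1.0 within a central circular plateau of radius
#' \code{radius} pixels, falling off outside it as a Gaussian with SD
#' \code{sigma}, on a square support extending \code{radius + 2 * sigma}
#' from the center on each side. The smooth skirt avoids introducing novel
#' edge features at the occluder boundary.
#'
#' @slot weights Square weight matrix in \code{[0,1]}.
#' @slot radius Plateau radius in pixels.
#' @slot sigma Gaussian falloff SD in pixels.
#' @slot width Support side length in pixels.
#' @slot background Background gray level occluded regions are pulled toward.
#' @export
setClass("BlobFilter",
  representation(weights = "matrix", radius = "numeric", sigma = "numeric",
                 width = "integer", background = "numeric"),
  validity = function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w)) return("support must be square")
    if (min(w) < 0 || max(w) > 1) return("weights must lie in [0,1]")
    cen <- (nrow(w) + 1) / 2
    d <- sqrt(outer((seq_len(nrow(w)) - cen)^2,
                    (seq_len(ncol(w)) - cen)^2, "+"))
    if (any(w[d <= object@radius] != 1))
      return("weights must equal 1 within the plateau radius")
    if (any(w[d > object@radius] >= 1))
      return("weights must be < 1 beyond the plateau radius")
    TRUE
  })

setMethod("show", "BlobFilter", function(object) {
  cat("BlobFilter:", object@width, "x", object@width, "px support, plateau r =",
      object@radius, "px, sigma =", object@sigma, "px, background =",
      object@background, "\n")
})

#' Radial blob weight profile
#' @param filter A \code{\linkS4class{BlobFilter}}.
#' @param d Distance(s) from the blob center in pixels.
#' @return Weight(s) in \code{[0,1]}.
#' @export
blobWeight <- function(filter, d) {
  ifelse(d <= filter@radius, 1,
         exp(-(d - filter@radius)^2 / (2 * filter@sigma^2)))
}

#' Build the blob occlusion filter
#'
#' Plateau radius and Gaussian SD default to 5\% of the image size (floored
#' to whole pixels), giving a 7 px radius and a 42 x 42 px support at the
#' standard 144 px working size.
#'
#' @param imageSize Image side length in pixels.
#' @param radiusFrac Plateau radius as a fraction of \code{imageSize}.
#' @param sigmaFrac Gaussian SD as a fraction of \code{imageSize}.
#' @param background Background gray level (default 0.5).
#' @return A \code{\linkS4class{BlobFilter}}.
#' @examples
#' buildBlobFilter(144)   # r = 7 px, support 42 x 42 px
#' @export
buildBlobFilter <- function(imageSize, radiusFrac = 0.05, sigmaFrac = 0.05,
                            background = 0.5) {
  if (radiusFrac <= 0 || radiusFrac >= 0.5 || sigmaFrac <= 0 || sigmaFrac >= 0.5)
    stop("configuration error: fractions must lie in (0, 0.5)")
  r <- floor(radiusFrac * imageSize)
  s <- floor(sigmaFrac * imageSize)
  if (r < 1 || s < 1)
    stop("configuration error: imageSize too small for the requested blob filter")
  width <- 2L * as.integer(r + 2 * s)
  cen <- (width + 1) / 2
  d <- sqrt(outer((seq_len(width) - cen)^2, (seq_len(width) - cen)^2, "+"))
  w <- matrix(ifelse(d <= r, 1, exp(-(d - r)^2 / (2 * s^2))), width, width)
  new("BlobFilter", weights = w, radius = r, sigma = s, width = width,
      background = background)
}

#' Number of blob applications for a given occlusion level
#'
#' The percent-occlusion parameter \code{O} in \code{[0,1]} maps to an
#' integer application count
#' \code{N = floor(2.5 * O * (imageSize / filterWidth + 1) + 0.5)}
#' (round-half-up of the underlying continuous rule), monotone
#' non-decreasing in \code{O} with \code{N(0) = 0}.
#'
#' @param O Occlusion fraction(s) in \code{[0,1]}.
#' @param imageSize Image side length in pixels.
#' @param filterWidth Blob filter support width in pixels.
#' @return Integer application count(s).
#' @examples
#' nApplications(c(0, 0.5, 1), 144, 42)  # 0, 6, 11
#' @export
nApplications <- function(O, imageSize = 144, filterWidth = 42) {
  if (any(!is.finite(O)) || any(O < 0) || any(O > 1))
    stop("invalid input: occlusion level O must lie in [0,1]")
  as.integer(floor(2.5 * O * (imageSize / filterWidth + 1) + 0.5))
}

#' Occlude an image with randomly placed blobs
#'
#' Applies \code{\link{nApplications}} blob placements at uniformly random
#' integer positions over the full image square (partial off-image blobs
#' allowed; fresh position per application). Overlapping placements combine
#' by per-pixel maximum of weights, so plateau regions are always exactly
#' the background gray. The output is
#' \code{w * background + (1 - w) * img} for the accumulated weight map
#' \code{w}.
#'
#' @param img Normalized image matrix.
#' @param filter A \code{\linkS4class{BlobFilter}} built for this image size.
#' @param O Occlusion level in \code{[0,1]}.
#' @param seed Optional integer seed for placement positions.
#' @return Occluded image matrix; \code{attr(, "weightMap")} carries the
#'   accumulated occlusion weights.
#' @export
occludeImage <- function(img, filter, O, seed = NULL) {
  stopifnot(is.matrix(img))
  n <- nApplications(O, nrow(img), filter@width)
  withSeed(seed, {
    wmap <- matrix(0, nrow(img), ncol(img))
    if (n > 0) {
      cen <- (filter@width + 1) / 2
      for (i in seq_len(n)) {
        cx <- sample.int(nrow(img), 1)
        cy <- sample.int(ncol(img), 1)
        xs <- cx + seq_len(filter@width) - ceiling(cen)
        ys <- cy + seq_len(filter@width) - ceiling(cen)
        okx <- xs >= 1 & xs <= nrow(img)
        oky <- ys >= 1 & ys <= ncol(img)
        wmap[xs[okx], ys[oky]] <- pmax(wmap[xs[okx], ys[oky]],
                                       filter@weights[which(okx), which(oky)])
      }
    }
    out <- wmap * filter@background + (1 - wmap) * img
    attr(out, "weightMap") <- wmap
    out
  })
}
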