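#' @include v1.R
NULL

#' Default biophysical constants of the rate-code point-neuron model
#'
#' Normalized-unit reversal potentials and integration constants for the
#' conductance-based membrane update
#' \code{V_m <- V_m + dt * (g_e (E_e - V_m) + g_i (E_i - V_m) + g_l (E_l - V_m))}
#' with activation a logistic function of \code{V_m - theta}. Ordering
#' \code{E_e > theta > E_l > E_i} (defaults 1.0, 0.5, 0.3, 0.15).
#'
#' @return Named list of constants: \code{eRev}, \code{theta}, \code{lRev},
#'   \code{iRev}, \code{gLeak}, \code{dt}, \code{gain}, \code{q} (kWTA
#'   interpolation point), \code{ffScale} (absolute strength of feedforward
#'   projections; sets the membrane time constant to a few cycles),
#'   \code{fbScale} (feedback strength relative to feedforward), \code{tol}
#'   and \code{maxCycles} (settling defaults).
#' @export
defaultNetParams <- function() {
  list(eRev = 1.0, theta = 0.5, lRev = 0.3, iRev = 0.15,
       gLeak = 0.1, dt = 0.3, gain = 300, q = 0.25, ffScale = 2,
       fbScale = 0.2, tol = 0.001, maxCycles = 60)
}

#' KwtaNetwork: recurrent rate-code network with kWTA inhibition
#'
#' Layered network mirroring the ventral pathway: a clamped V1 input layer,
#' hidden layers (V2/V4, IT), a one-unit-per-category output layer and an
#' optional semantics layer bidirectionally linked to IT. All adjacent
#' layers are reciprocally connected; each feedforward projection between
#' hidden layers has a feedback twin whose transmission is scaled by
#' \code{fbScale * fbGain} (\code{fbGain = 0} silences feedback exactly).
#'
#' @slot layers Data frame: \code{name}, \code{n} (units), \code{k} (kWTA
#'   winner count), \code{type} (input/hidden/output/semantics).
#' @slot projections List of projections: \code{from}, \code{to},
#'   \code{W} (sender x receiver weight matrix in \code{[0,1]}),
#'   \code{type} (\code{"ff"}/\code{"fb"}), \code{fbGain}.
#' @slot params Constants as in \code{\link{defaultNetParams}}.
#' @slot bank The \code{\linkS4class{FilterBank}} front-end this network
#'   expects its V1 input from.
#' @slot imageSize Working image size in pixels.
#' @slot kwtaPct Front-end sparsity bound used by \code{\link{v1Encode}}.
#' @slot categories Category labels (one output unit each).
#' @slot seed Integer seed used for weight initialization.
#' @export
setClass("KwtaNetwork",
  representation(layers = "data.frame", projections = "list",
                 params = "list", bank = "FilterBank", imageSize = "integer",
                 kwtaPct = "numeric", categories = "character",
                 seed = "integer"),
  validity = function(object) {
    ly <- object@layers
    if (any(ly$k > ly$n)) return("k must not exceed layer size")
    for (pr in object@projections) {
      if (!pr$from %in% ly$name || !pr$to %in% ly$name)
        return("projection endpoints must be declared layers")
      if (min(pr$W) < 0 || max(pr$W) > 1) return("weights must lie in [0,1]")
      if (pr$to == "V1") return("V1 receives no feedback in this architecture")
    }
    TRUE
  })

setMethod("show", "KwtaNetwork", function(object) {
  cat("KwtaNetwork:", nrow(object@layers), "layers (",
      paste0(object@layers$name, "[", object@layers$n, ",k=", object@layers$k,
             "]", collapse = " "), ")\n  ",
      length(object@projections), "projections;",
      length(object@categories), "categories; image size",
      object@imageSize, "px\n")
})

#' Accessors for KwtaNetwork
#' @param object A \code{\linkS4class{KwtaNetwork}}.
#' @return \code{layerNames}: character vector; \code{layerSize}: unit count;
#'   \code{projectionWeights}: weight matrix of the named projection.
#' @export
layerNames <- function(object) object@layers$name

#' @rdname layerNames
#' @param layer Layer name.
#' @export
layerSize <- function(object, layer) {
  object@layers$n[match(layer, object@layers$name)]
}

#' @rdname layerNames
#' @param from,to Sender / receiver layer names.
#' @param type Projection type ("ff" or "fb").
#' @export
projectionWeights <- function(object, from, to, type = NULL) {
  for (pr in object@projections)
    if (pr$from == from && pr$to == to && (is.null(type) || pr$type == type))
      return(pr$W)
  stop("no projection ", from, " -> ", to)
}

#' Specify the recurrent network architecture
#'
#' @param bank Front-end \code{\linkS4class{FilterBank}}.
#' @param imageSize Working image size in pixels.
#' @param categories Category labels.
#' @param v2Size,itSize Hidden layer unit counts.
#' @param semSize Semantics layer unit count, or \code{NULL} to omit the
#'   semantics layer.
#' @param kwtaPct Activity fraction for hidden layers and the front-end
#'   (default 0.15).
#' @param semPct Semantics activity fraction (default 0.25, matching the
#'   semantic pattern sparsity).
#' @param params Constants, see \code{\link{defaultNetParams}}.
#' @return A network spec list consumed by \code{\link{buildNetwork}}.
#' @export
kwtaNetworkSpec <- function(bank, imageSize, categories, v2Size = 120,
                            itSize = 80, semSize = NULL, kwtaPct = 0.15,
                            semPct = 0.25, params = defaultNetParams()) {
  list(bank = bank, imageSize = as.integer(imageSize),
       categories = as.character(categories), v2Size = v2Size, itSize = itSize,
       semSize = semSize, kwtaPct = kwtaPct, semPct = semPct, params = params)
}

#' Build a recurrent kWTA network
#'
#' Creates layers V1 (input), V2 (standing in for V2/V4), IT, Output and
#' optionally Semantics, with reciprocal projections between adjacent
#' layers (V1 -> V2 feedforward only; V2 <-> IT; IT <-> Output;
#' IT <-> Semantics). Weights are initialized uniformly in
#' \code{mean +/- range} (defaults 0.5 +/- 0.25), deterministic given the
#' seed.
#'
#' @param spec Spec from \code{\link{kwtaNetworkSpec}}.
#' @param seed Integer seed.
#' @param initMean,initRange Weight initialization parameters.
#' @return A \code{\linkS4class{KwtaNetwork}}.
#' @export
buildNetwork <- function(spec, seed = 1, initMean = 0.5, initRange = 0.25) {
  nV1 <- v1Size(spec$bank, spec$imageSize)
  nOut <- length(spec$categories)
  layers <- data.frame(
    name = c("V1", "V2", "IT", "Output"),
    n = c(nV1, spec$v2Size, spec$itSize, nOut),
    k = c(max(1, floor(spec$kwtaPct * nV1)),
          max(1, floor(spec$kwtaPct * spec$v2Size)),
          max(1, floor(spec$kwtaPct * spec$itSize)), 1),
    type = c("input", "hidden", "hidden", "output"),
    stringsAsFactors = FALSE)
  edges <- list(c("V1", "V2"), c("V2", "IT"), c("IT", "Output"))
  if (!is.null(spec$semSize)) {
    layers <- rbind(layers, data.frame(
      name = "Semantics", n = spec$semSize,
      k = max(1, round(spec$semPct * spec$semSize)), type = "semantics"))
    edges <- c(edges, list(c("IT", "Semantics")))
  }
  if (any(layers$k > layers$n))
    stop("configuration error: k exceeds layer size")
  withSeed(seed, {
    projections <- list()
    for (e in edges) {
      nf <- layers$n[layers$name == e[1]]; nt <- layers$n[layers$name == e[2]]
      # each receiving unit's incoming mean is equalized at initMean so that
      # initial winners reflect input-pattern overlap, not random mean-weight
      # differences between units (selectivity then develops through learning)
      mk <- function(a, b) {
        W <- matrix(runif(a * b, initMean - initRange, initMean + initRange), a, b)
        W <- W + rep(initMean - colMeans(W), each = a)
        matrix(pmin(1, pmax(0, W)), a, b)
      }
      projections <- c(projections, list(
        list(from = e[1], to = e[2], W = mk(nf, nt), type = "ff", fbGain = 1)))
      if (e[1] != "V1")
        projections <- c(projections, list(
          list(from = e[2], to = e[1], W = mk(nt, nf), type = "fb", fbGain = 1)))
    }
    new("KwtaNetwork", layers = layers, projections = projections,
        params = spec$params, bank = spec$bank, imageSize = spec$imageSize,
        kwtaPct = spec$kwtaPct, categories = spec$categories,
        seed = as.integer(seed))
  })
}

#' Silence all feedback projections
#'
#' Sets \code{fbGain = 0} on every feedback projection, exactly removing
#' top-down excitatory transmission while leaving the weights untouched, so
#' the lesion is restorable with \code{restoreFeedback}.
#'
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @return The lesioned (or restored) network.
#' @export
lesionFeedback <- function(net) {
  net@projections <- lapply(net@projections, function(pr) {
    if (pr$type == "fb") pr$fbGain <- 0
    pr
  })
  net
}

#' @rdname lesionFeedback
#' @export
restoreFeedback <- function(net) {
  net@projections <- lapply(net@projections, function(pr) {
    if (pr$type == "fb") pr$fbGain <- 1
    pr
  })
  net
}

# -- dynamics ----------------------------------------------------------------

actFun <- function(vm, params) plogis(params$gain * (vm - params$theta))

#' Initialize network state
#'
#' All membrane potentials start at the leak reversal potential; activations
#' follow from the activation function (effectively zero).
#'
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @return Named list per layer of \code{list(vm, act)}.
#' @export
initState <- function(net) {
  st <- lapply(seq_len(nrow(net@layers)), function(i) {
    n <- net@layers$n[i]
    list(vm = rep(net@params$lRev, n), act = rep(actFun(net@params$lRev, net@params), n))
  })
  names(st) <- net@layers$name
  st
}

#' kWTA shared inhibitory conductance
#'
#' Computes the per-unit threshold conductance \code{gTheta} (the inhibition
#' that would hold each unit exactly at threshold given its excitatory
#' drive) and places the layer's shared inhibition between the k-th and
#' (k+1)-th values: \code{g_i = gTheta(k+1) + q (gTheta(k) - gTheta(k+1))}.
#' At equilibrium at most k units can then exceed threshold. If
#' \code{k >= n} the inhibition is set below the weakest unit (all may be
#' active).
#'
#' @param ge Per-unit excitatory conductances.
#' @param k Winner count (>= 1).
#' @param params Constants (see \code{\link{defaultNetParams}}).
#' @param q Interpolation point in \code{[0,1]} (default from params, 0.25).
#' @return Scalar inhibitory conductance (floored at 0).
#' @export
kwtaInhibition <- function(ge, k, params = defaultNetParams(), q = params$q) {
  if (k < 1) stop("k must be >= 1")
  gThr <- thresholdConductance(ge, params)
  if (k >= length(ge)) return(max(0, min(gThr) * 0.9))
  srt <- sort(gThr, decreasing = TRUE)
  max(0, srt[k + 1] + q * (srt[k] - srt[k + 1]))
}

# inhibition that holds a unit with drive ge exactly at threshold
thresholdConductance <- function(ge, params) {
  (ge * (params$eRev - params$theta) +
     params$gLeak * (params$lRev - params$theta)) / (params$theta - params$iRev)
}

# minimal g_i such that, after this cycle's V_m step, at most k units lie
# strictly above threshold; closed form because the stepped V_m is linear in
# g_i (fast within-cycle inhibition; see the methods vignette)
fastInhibition <- function(vm, ge, k, params) {
  with(params, {
    drive <- vm + dt * (ge * (eRev - vm) + gLeak * (lRev - vm))
    denom <- pmax(dt * (vm - iRev), 1e-12)
    req <- (drive - theta) / denom
    if (k >= length(req)) return(0)
    # tiny margin keeps the boundary unit strictly at/below threshold in the
    # face of floating-point noise
    sort(req, decreasing = TRUE)[k + 1] + 1e-9
  })
}

# excitatory conductance for each layer from the previous cycle's activations;
# normalized by the sender's expected active count, feedback scaled by
# fbScale * fbGain
computeGe <- function(net, acts) {
  ge <- lapply(net@layers$n, numeric)
  names(ge) <- net@layers$name
  expAct <- setNames(pmax(net@layers$k, 1), net@layers$name)
  for (pr in net@projections) {
    scale <- net@params$ffScale *
      (if (pr$type == "fb") net@params$fbScale * pr$fbGain else 1)
    if (scale == 0) next
    contrib <- as.numeric(crossprod(pr$W, acts[[pr$from]])) / expAct[[pr$from]]
    ge[[pr$to]] <- ge[[pr$to]] + scale * contrib
  }
  ge
}

#' Advance the network by one cycle
#'
#' Synchronous update: every free layer's excitatory conductance is computed
#' from the previous cycle's activations, inhibition is set by
#' \code{\link{kwtaInhibition}} (raised if needed so at most k units cross
#' threshold this cycle), membrane potentials are integrated one step, and
#' activations follow from the logistic activation function. Clamped layers
#' keep their clamp values.
#'
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @param state State list as from \code{\link{initState}}.
#' @param clamps Named list of activation vectors for clamped layers.
#' @return Updated state list.
#' @export
updateCycle <- function(net, state, clamps = list()) {
  pm <- net@params
  acts <- lapply(state, `[[`, "act")
  ge <- computeGe(net, acts)
  for (i in seq_len(nrow(net@layers))) {
    nm <- net@layers$name[i]
    if (nm %in% names(clamps)) {
      a <- clamps[[nm]]
      if (length(a) != net@layers$n[i]) stop("clamp size mismatch for ", nm)
      state[[nm]]$act <- a
      state[[nm]]$vm <- pm$theta + ifelse(a > 0.5, 0.2, -0.2)
      next
    }
    vm <- state[[nm]]$vm
    g <- ge[[nm]]
    gi <- max(kwtaInhibition(g, net@layers$k[i], pm),
              fastInhibition(vm, g, net@layers$k[i], pm))
    vm <- vm + pm$dt * (g * (pm$eRev - vm) + gi * (pm$iRev - vm) +
                          pm$gLeak * (pm$lRev - vm))
    if (any(!is.finite(vm)))
      stop("simulation error: non-finite membrane potential in layer ", nm)
    state[[nm]]$vm <- vm
    state[[nm]]$act <- actFun(vm, pm)
  }
  state
}

#' Settle the network to a stable state
#'
#' Repeats \code{\link{updateCycle}} until the maximum per-unit activation
#' change falls below \code{tol} or \code{maxCycles} is reached.
#'
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @param clamps Named list of clamped layer activations (V1 at minimum).
#' @param state Optional starting state (defaults to \code{\link{initState}}).
#' @param maxCycles,tol Stopping parameters (defaults from the network's
#'   params: 60 cycles, 0.005).
#' @param record Keep per-cycle activation snapshots.
#' @return List: \code{state}, \code{cycles}, \code{converged}, and (if
#'   recorded) \code{snapshots} -- a list per cycle of per-layer activations.
#' @export
settle <- function(net, clamps, state = NULL, maxCycles = net@params$maxCycles,
                   tol = net@params$tol, record = FALSE) {
  stopifnot(maxCycles >= 1)
  if (is.null(state)) state <- initState(net)
  snapshots <- if (record) vector("list", maxCycles) else NULL
  converged <- FALSE
  cycles <- 0
  for (cy in seq_len(maxCycles)) {
    prev <- state
    state <- updateCycle(net, state, clamps)
    cycles <- cy
    if (record) snapshots[[cy]] <- lapply(state, `[[`, "act")
    # track membrane potential too: activations barely move while V_m is
    # still charging toward threshold, so act change alone stops too early
    delta <- max(vapply(names(state), function(nm)
      max(abs(state[[nm]]$act - prev[[nm]]$act),
          abs(state[[nm]]$vm - prev[[nm]]$vm)), numeric(1)))
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- list(state = state, cycles = cycles, converged = converged)
  if (record) out$snapshots <- snapshots[seq_len(cycles)]
  out
}

#' Clamp built from an encoded image
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @param img Normalized image matrix.
#' @return Named list with the V1 clamp vector.
#' @export
v1Clamp <- function(net, img) {
  list(V1 = v1Vector(v1Encode(img, net@bank, net@kwtaPct)))
}

#' One-hot output clamp for a category
#' @param net A \code{\linkS4class{KwtaNetwork}}.
#' @param category Category label.
#' @return Numeric one-hot vector over output units.
#' @export
outputClamp <- function(net, category) {
  i <- match(category, net@categories)
  if (is.na(i)) stop("unknown category: ", category)
  v <- numeric(length(net@categories)); v[i] <- 1
  v
}
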