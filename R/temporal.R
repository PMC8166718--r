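#' Initialize weights for the 3D-convolution temporal front
#'
#' The front holds \code{nK} kernels of size \code{r x 3 x 3} applied over
#' all \code{nC} colour channels of a frame triplet, i.e.
#' \code{nK * (r*3*3*nC)} weights plus \code{nK} biases. Two initializations
#' are provided: \code{"he"} (random, for end-to-end training) and
#' \code{"temporal_mean"} (requires \code{nK = 3}; each output channel is
#' the across-time mean of the matching colour channel, a temporal denoiser
#' that feeds a fixed-input core unchanged in expectation).
#'
#' @param spec a \linkS4class{TemporalExtensionSpec}.
#' @param nC colour channels per frame (3).
#' @param init \code{"he"} or \code{"temporal_mean"}.
#' @param seed seed for random initialization.
#' @return list with matrix \code{W} (\code{(r*3*3*nC) x nK}) and bias
#'   \code{b}.
#' @export
frontWeights <- function(spec, nC = 3L, init = c("he", "temporal_mean"),
                         seed = 1L) {
  init <- match.arg(init)
  validObject(spec)
  nK <- spec@nK
  rows <- 9L * spec@r * nC
  if (init == "he") {
    W <- with_seed(seed,
      matrix(stats::rnorm(rows * nK, sd = sqrt(2 / rows)), rows, nK))
  } else {
    if (nK != 3L)
      stop("temporal_mean initialization requires nK = 3 (one kernel per ",
           "colour channel)")
    W <- matrix(0, rows, nK)
    for (k in 0:(spec@r * nC - 1L)) {
      colr <- k %% nC          # colour of input channel k (frame-major order)
      W[9L * k + 5L, colr + 1L] <- 1 / spec@r  # centre tap (dx = dy = 1)
    }
  }
  list(W = W, b = numeric(nK))
}

# Forward pass of the front on a stacked triplet batch (h, w, r*nC, n):
# valid 3x3 convolution (the temporal extent equals r, so no temporal
# dimension survives), activation, then a one-pixel zero ring restoring
# (h, w, nK, n).
front_fwd <- function(x9, W, b, activation) {
  d <- dim(x9)
  raw <- conv3_fwd(x9, W, b, pad = 0L)
  if (activation == "relu") {
    r <- relu_fwd(raw); act <- r$y; mask <- r$mask
  } else { act <- raw; mask <- NULL }
  out <- array(0, c(d[1L], d[2L], ncol(W), d[4L]))
  out[2:(d[1L] - 1L), 2:(d[2L] - 1L), , ] <- act
  list(y = out, cache = list(x9 = x9, mask = mask, d = d),
       rawDim = c(1L, d[1L] - 2L, d[2L] - 2L, ncol(W)))
}

front_bwd <- function(cache, W, dy) {
  d <- cache$d
  draw <- dy[2:(d[1L] - 1L), 2:(d[2L] - 1L), , , drop = FALSE]
  if (!is.null(cache$mask)) draw <- relu_bwd(cache$mask, draw)
  r <- conv3_bwd(cache$x9, W, draw, pad = 0L)
  list(dW = r$dW, db = r$db)
}

#' Apply the 3D-convolution temporal front to one frame triplet
#'
#' Computes the raw valid 3D convolution of the triplet -- output shape
#' \code{(1, p-2, q-2, nK)} -- then restores the spatial dimensions with a
#' one-pixel zero ring and squeezes the singleton temporal axis, returning a
#' \code{p x q x nK} feature map whose border ring is exactly zero. The raw
#' pre-padding shape is attached as attribute \code{"rawDim"}.
#'
#' @param triplet a \linkS4class{FrameTriplet} with \code{p, q >= 3}.
#' @param spec a \linkS4class{TemporalExtensionSpec}.
#' @param weights list \code{(W, b)} from \code{\link{frontWeights}}.
#' @return numeric array \code{p x q x nK} with attribute \code{rawDim}.
#' @examples
#' fr <- lapply(0:2, function(t) Frame(array(runif(8*8*3), c(8, 8, 3)), t = t))
#' tri <- makeTriplets(fr, "drop_edges")[[1]]
#' sp <- TemporalExtensionSpec(nK = 4)
#' h <- temporalFront(tri, sp, frontWeights(sp, seed = 1))
#' attr(h, "rawDim")  # (1, 6, 6, 4)
#' @export
temporalFront <- function(triplet, spec, weights) {
  stopifnot(is(triplet, "FrameTriplet"), is(spec, "TemporalExtensionSpec"))
  validObject(spec)
  d <- dim(triplet@frames[[1L]]@pixels)
  if (d[1L] < 3L || d[2L] < 3L)
    stop("spatial dims must be at least 3 x 3 for the (r x 3 x 3) kernel")
  x9 <- stack_triplet(triplet)
  fw <- front_fwd(x9, weights$W, weights$b, spec@activation)
  out <- array(fw$y, dim(fw$y)[1:3])
  attr(out, "rawDim") <- fw$rawDim
  out
}

#' Extend a single-frame core model with a temporal front
#'
#' Prepends the 3D-convolution front to a core model, producing a
#' multi-frame model that maps a frame triplet to the segmentation of its
#' central frame. For a residual U-Net core the front is He-initialized and
#' trained end-to-end with the core; its kernel count \code{nK} must match
#' the core's input channels. For the fixed-input instance core only
#' \code{nK = 3} can match the predefined input size; its front starts as
#' the across-time mean of each colour channel.
#'
#' @param core a \linkS4class{ResUNetModel} or \linkS4class{InstanceSegModel}.
#' @param spec a \linkS4class{TemporalExtensionSpec}.
#' @param seed seed for front initialization (ResUNet core).
#' @param tag model tag; defaults to \code{"M1"} or \code{"M2"} by core type.
#' @return An \linkS4class{ExtendedModel}.
#' @examples
#' core <- buildResUNet(ResUNetSpec(depth = 3, baseFilters = 16,
#'                                  inputShape = c(64, 64, 3)))
#' M1 <- extendModel(core, TemporalExtensionSpec(nK = 3))
#' @export
extendModel <- function(core, spec = TemporalExtensionSpec(), seed = 1L,
                        tag = NULL) {
  validObject(spec)
  if (is(core, "InstanceSegModel")) {
    if (spec@nK != core@spec@inputChannels)
      stop("configuration error: the fixed-input core requires nK = ",
           core@spec@inputChannels)
    front <- frontWeights(spec, nC = 3L, init = "temporal_mean")
    if (is.null(tag)) tag <- "M2"
  } else if (is(core, "ResUNetModel")) {
    if (spec@nK != core@spec@inputShape[3L])
      stop("configuration error: core expects ", core@spec@inputShape[3L],
           " input channels but nK = ", spec@nK)
    front <- frontWeights(spec, nC = 3L, init = "he", seed = seed)
    if (is.null(tag)) tag <- "M1"
  } else stop("unsupported core model class: ", class(core))
  new("ExtendedModel", frontSpec = spec, front = front, core = core,
      tag = tag)
}

#' @describeIn extendModel Parameter count: core parameters plus
#'   \code{nK*(r*3*3*nC) + nK} front weights.
#' @param model an \linkS4class{ExtendedModel}.
#' @export
setMethod("parameterCount", "ExtendedModel",
  function(model)
    as.integer(length(model@front$W) + length(model@front$b) +
                 parameterCount(model@core)))

# Joint forward of front + residual U-Net core on stacked triplets
# (h, w, 9, n). Returns probabilities, caches, refreshed params.
extended_fwd <- function(model, x9, training = FALSE) {
  fw <- front_fwd(std_batch(x9), model@front$W, model@front$b,
                  model@frontSpec@activation)
  cw <- resunet_fwd(model@core@params, model@core@spec, fw$y,
                    training = training)
  list(p = cw$p, frontCache = fw$cache, coreCache = cw$cache,
       coreParams = cw$params)
}

extended_bwd <- function(model, caches, dp) {
  rc <- resunet_bwd(model@core@params, model@core@spec, caches$coreCache, dp)
  gf <- front_bwd(caches$frontCache, model@front$W, rc$dx)
  list(front = list(W = gf$dW, b = gf$db), core = rc$g)
}

#' @rdname predictTriplet
setMethod("predictTriplet", c("ExtendedModel", "FrameTriplet"),
  function(model, triplet, ...) {
    d <- dim(triplet@frames[[1L]]@pixels)
    native <- d[1:2]
    if (is(model@core, "ResUNetModel")) {
      ws <- model@core@spec@inputShape
      frames <- triplet@frames
      if (any(native != ws[1:2]))
        frames <- lapply(frames, function(f) {
          f@pixels <- resize_bilinear(f@pixels, ws[1L], ws[2L]); f
        })
      x9 <- array(0, c(dim(frames[[1L]]@pixels)[1:2], 9L, 1L))
      for (f in 1:3)
        x9[, , (3L * (f - 1L) + 1L):(3L * f), 1L] <- frames[[f]]@pixels
      p <- extended_fwd(model, x9, training = FALSE)$p
      p <- array(p, dim(p)[1:2])
      if (any(native != ws[1:2]))
        p <- resize_bilinear(p, native[1L], native[2L])
      ProbabilityMap(pmin(pmax(p, 0), 1), t = triplet@centerIndex,
                     modelTag = model@tag)
    } else {
      x9 <- stack_triplet(triplet)
      fw <- front_fwd(x9, model@front$W, model@front$b,
                      model@frontSpec@activation)
      px <- pmin(pmax(array(fw$y, dim(fw$y)[1:3]), 0), 1)
      pr <- propose_instances(px, model@core@params,
                              model@core@spec@anchorScales)
      instancesToLumenMap(pr$masks, pr$scores,
        confidenceThreshold = model@core@spec@minDetectionConfidence,
        mergePolicy = model@core@params$mergePolicy,
        t = triplet@centerIndex, modelTag = model@tag)
    }
  })
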