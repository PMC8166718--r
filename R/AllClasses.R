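#' @useDynLib LumenSeg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## ---------------------------------------------------------------------------
## Frames, masks, probability maps
## ---------------------------------------------------------------------------

#' Frame: one normalized RGB video frame
#'
#' A single endoscopic video frame with pixel values in \code{[0, 1]}, its
#' temporal index within the video, and provenance (video and patient
#' identifiers) used for leakage-free patient-wise splits.
#'
#' @slot pixels numeric array of shape \code{p x q x 3} with values in
#'   \code{[0, 1]}.
#' @slot t non-negative integer frame index within the video.
#' @slot videoId character scalar.
#' @slot patientId character scalar.
#' @export
setClass("Frame",
  representation(pixels = "array", t = "integer", videoId = "character",
                 patientId = "character"))

setValidity("Frame", function(object) {
  px <- object@pixels
  if (length(dim(px)) != 3L) return("pixels must be a p x q x 3 array")
  if (dim(px)[3L] != 3L) return("frames must have 3 (RGB) channels")
  if (dim(px)[1L] < 8L || dim(px)[2L] < 8L)
    return("spatial dims must be at least 8 x 8")
  rng <- range(px)
  if (rng[1L] < 0 || rng[2L] > 1) return("pixel values must lie in [0, 1]")
  if (object@t < 0L) return("frame index t must be non-negative")
  TRUE
})

#' Construct a Frame
#'
#' @param pixels numeric array \code{p x q x 3} in \code{[0, 1]}; a
#'   \code{p x q} matrix is replicated across the three channels.
#' @param t integer frame index (0-based within the video).
#' @param videoId,patientId provenance identifiers.
#' @return A validated \linkS4class{Frame}.
#' @examples
#' f <- Frame(array(0.5, c(16, 16, 3)), t = 0L)
#' dim(pixels(f))
#' @export
Frame <- function(pixels, t = 0L, videoId = "v1", patientId = "p1") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  new("Frame", pixels = pixels, t = as.integer(t),
      videoId = as.character(videoId), patientId = as.character(patientId))
}

#' FrameTriplet: three consecutive frames around a center frame
#'
#' Input unit for the multi-frame models: the ordered triple
#' \code{(I(t-1), I(t), I(t+1))} from one video. At video boundaries the edge
#' frame may be replicated; \code{boundaryFlag} records which side, if any.
#'
#' @slot frames list of exactly three \linkS4class{Frame} objects with
#'   identical spatial dims and the same \code{videoId}.
#' @slot centerIndex integer, the temporal index of the middle frame.
#' @slot boundaryFlag one of \code{"interior"}, \code{"replicated_left"},
#'   \code{"replicated_right"}.
#' @export
setClass("FrameTriplet",
  representation(frames = "list", centerIndex = "integer",
                 boundaryFlag = "character"))

setValidity("FrameTriplet", function(object) {
  fr <- object@frames
  if (length(fr) != 3L) return("a triplet holds exactly 3 frames")
  if (!all(vapply(fr, is, TRUE, "Frame"))) return("all elements must be Frames")
  dd <- vapply(fr, function(f) dim(f@pixels), integer(3L))
  if (any(dd != dd[, 1L])) return("frames must share p, q, n_c")
  vid <- vapply(fr, function(f) f@videoId, "")
  if (length(unique(vid)) != 1L) return("frames must come from one video")
  if (!object@boundaryFlag %in%
        c("interior", "replicated_left", "replicated_right"))
    return("invalid boundaryFlag")
  if (object@centerIndex != fr[[2L]]@t)
    return("centerIndex must equal the middle frame's t")
  TRUE
})

#' BinaryMask: ground-truth or predicted binary lumen mask
#'
#' @slot pixels numeric matrix \code{p x q} with values exactly 0 or 1.
#' @slot t integer frame index.
#' @slot videoId character scalar.
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", t = "integer", videoId = "character"))

setValidity("BinaryMask", function(object) {
  if (!all(object@pixels %in% c(0, 1)))
    return("mask values must be exactly 0 or 1")
  TRUE
})

#' Construct a BinaryMask
#' @param pixels numeric \code{p x q} matrix of 0/1 values.
#' @param t integer frame index.
#' @param videoId character scalar.
#' @return A validated \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(pixels, t = 0L, videoId = "v1") {
  new("BinaryMask", pixels = pixels, t = as.integer(t),
      videoId = as.character(videoId))
}

#' ProbabilityMap: per-pixel lumen probability for one frame
#'
#' @slot pixels numeric matrix \code{p x q} with values in \code{[0, 1]}.
#' @slot t integer frame index.
#' @slot modelTag character, which model produced the map
#'   (\code{"m1"}, \code{"m2"}, \code{"M1"}, \code{"M2"}, \code{"ensemble"}).
#' @export
setClass("ProbabilityMap",
  representation(pixels = "matrix", t = "integer", modelTag = "character"))

setValidity("ProbabilityMap", function(object) {
  rng <- range(object@pixels)
  if (rng[1L] < 0 || rng[2L] > 1) return("probabilities must lie in [0, 1]")
  TRUE
})

#' Construct a ProbabilityMap
#' @param pixels numeric \code{p x q} matrix in \code{[0, 1]}.
#' @param t integer frame index.
#' @param modelTag producing model's tag.
#' @return A validated \linkS4class{ProbabilityMap}.
#' @export
ProbabilityMap <- function(pixels, t = 0L, modelTag = "model") {
  new("ProbabilityMap", pixels = pixels, t = as.integer(t),
      modelTag = as.character(modelTag))
}

#' ConfusionCounts: per-frame pixel confusion tallies
#'
#' Counts of true-positive, false-positive, false-negative and true-negative
#' pixels for one predicted/reference mask pair; the sufficient statistics for
#' the Dice coefficient, precision and recall.
#'
#' @slot tp,fp,fn,tn non-negative pixel counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0)) return("counts must be non-negative")
  if (any(v != round(v))) return("counts must be integers")
  TRUE
})

#' Construct ConfusionCounts
#' @param tp,fp,fn,tn non-negative integer pixel counts.
#' @return A validated \linkS4class{ConfusionCounts}.
#' @examples
#' ConfusionCounts(tp = 6, fp = 2, fn = 2, tn = 54)
#' @export
ConfusionCounts <- function(tp, fp, fn, tn) {
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn))
}

## ---------------------------------------------------------------------------
## Specs
## ---------------------------------------------------------------------------

#' AugmentationParams: one sampled geometric augmentation
#'
#' Quarter-turn rotation count, horizontal/vertical flips and a zoom factor
#' within two percent of unity, applied jointly to an image (or triplet) and
#' its mask.
#'
#' @slot rotationQuarterTurns integer in \code{0:3}.
#' @slot hflip,vflip logical flips.
#' @slot zoomFactor numeric in \code{[0.98, 1.02]}.
#' @slot seed integer seed the parameters were drawn with.
#' @export
setClass("AugmentationParams",
  representation(rotationQuarterTurns = "integer", hflip = "logical",
                 vflip = "logical", zoomFactor = "numeric", seed = "integer"))

setValidity("AugmentationParams", function(object) {
  if (!object@rotationQuarterTurns %in% 0:3)
    return("rotation must be 0..3 quarter turns")
  if (object@zoomFactor < 0.98 || object@zoomFactor > 1.02)
    return("zoomFactor must lie in [0.98, 1.02]")
  TRUE
})

#' Construct AugmentationParams directly
#' @param rotationQuarterTurns integer in \code{0:3}.
#' @param hflip,vflip logical.
#' @param zoomFactor numeric in \code{[0.98, 1.02]}.
#' @param seed integer provenance seed.
#' @return An \linkS4class{AugmentationParams}.
#' @export
AugmentationParams <- function(rotationQuarterTurns = 0L, hflip = FALSE,
                               vflip = FALSE, zoomFactor = 1.0, seed = 0L) {
  new("AugmentationParams",
      rotationQuarterTurns = as.integer(rotationQuarterTurns),
      hflip = hflip, vflip = vflip, zoomFactor = zoomFactor,
      seed = as.integer(seed))
}

#' ResUNetSpec: architecture of the residual U-Net core (m1)
#'
#' Encoder--decoder with skip connections where every block is a residual
#' unit: two 3x3 convolutions plus an identity shortcut (1x1 projection when
#' channel counts differ). Filters double at each encoder level.
#'
#' @slot depth integer number of encoder levels (>= 2); inputs must be
#'   divisible by \code{2^depth}.
#' @slot baseFilters integer (>= 8) filters at the first level.
#' @slot inputShape integer(3), \code{c(p, q, channels)}.
#' @slot useBatchNorm logical, batch normalization inside residual units.
#' @export
setClass("ResUNetSpec",
  representation(depth = "integer", baseFilters = "integer",
                 inputShape = "integer", useBatchNorm = "logical"))

setValidity("ResUNetSpec", function(object) {
  if (object@depth < 2L) return("depth must be >= 2")
  if (object@baseFilters < 8L) return("baseFilters must be >= 8")
  if (length(object@inputShape) != 3L) return("inputShape must be (p, q, c)")
  d <- 2L^object@depth
  if (object@inputShape[1L] %% d != 0L || object@inputShape[2L] %% d != 0L)
    return(sprintf("input dims must be divisible by 2^depth = %d", d))
  TRUE
})

#' Construct a ResUNetSpec
#' @param depth encoder levels (default 4).
#' @param baseFilters filters at level 1 (default 32).
#' @param inputShape integer(3) \code{c(p, q, channels)}.
#' @param useBatchNorm logical (default \code{TRUE}).
#' @return A validated \linkS4class{ResUNetSpec}.
#' @examples
#' ResUNetSpec(depth = 3, baseFilters = 16, inputShape = c(64, 64, 3))
#' @export
ResUNetSpec <- function(depth = 4L, baseFilters = 32L,
                        inputShape = c(256L, 256L, 3L),
                        useBatchNorm = TRUE) {
  new("ResUNetSpec", depth = as.integer(depth),
      baseFilters = as.integer(baseFilters),
      inputShape = as.integer(inputShape), useBatchNorm = useBatchNorm)
}

#' InstanceSegSpec: configuration of the instance-segmentation core (m2)
#'
#' Settings for the proposal-based instance core: backbone label, the minimal
#' detection confidence below which instances are discarded, and the anchor
#' scales covering the range of lumen sizes.
#'
#' @slot backbone \code{"resnet50"} or \code{"resnet101"}.
#' @slot minDetectionConfidence numeric in \code{[0.5, 0.9]}.
#' @slot anchorScales strictly increasing positive integers
#'   (default 32, 64, 128, 160).
#' @slot inputChannels integer, channels the core expects (3).
#' @export
setClass("InstanceSegSpec",
  representation(backbone = "character", minDetectionConfidence = "numeric",
                 anchorScales = "integer", inputChannels = "integer"))

setValidity("InstanceSegSpec", function(object) {
  if (!object@backbone %in% c("resnet50", "resnet101"))
    return("backbone must be resnet50 or resnet101")
  if (object@minDetectionConfidence < 0.5 ||
      object@minDetectionConfidence > 0.9)
    return("minDetectionConfidence must lie in [0.5, 0.9]")
  a <- object@anchorScales
  if (any(a <= 0L) || any(diff(a) <= 0L))
    return("anchorScales must be strictly increasing and positive")
  TRUE
})

#' Construct an InstanceSegSpec
#' @param backbone backbone label.
#' @param minDetectionConfidence minimal score for an instance to survive.
#' @param anchorScales increasing positive integer scales.
#' @param inputChannels channels expected by the core (fixed 3 in practice).
#' @return A validated \linkS4class{InstanceSegSpec}.
#' @export
InstanceSegSpec <- function(backbone = "resnet50",
                            minDetectionConfidence = 0.7,
                            anchorScales = c(32L, 64L, 128L, 160L),
                            inputChannels = 3L) {
  new("InstanceSegSpec", backbone = backbone,
      minDetectionConfidence = minDetectionConfidence,
      anchorScales = as.integer(anchorScales),
      inputChannels = as.integer(inputChannels))
}

#' TemporalExtensionSpec: the 3D-convolution front of the multi-frame models
#'
#' A core model is extended to a multi-frame model by prepending one 3D
#' convolution with \code{nK} kernels of size \code{r x 3 x 3} (temporal
#' extent \code{r = 3}) applied to a frame triplet; the valid convolution
#' output of shape \code{(1, p-2, q-2, nK)} is zero-padded back to
#' \code{(p, q, nK)} before entering the core.
#'
#' @slot r integer temporal extent, fixed at 3.
#' @slot nK integer number of kernels (>= 1).
#' @slot kernelSpatial integer(2), fixed \code{c(3, 3)}.
#' @slot activation \code{"relu"} or \code{"linear"} after the convolution.
#' @export
setClass("TemporalExtensionSpec",
  representation(r = "integer", nK = "integer", kernelSpatial = "integer",
                 activation = "character"))

setValidity("TemporalExtensionSpec", function(object) {
  if (object@r != 3L) return("temporal extent r is fixed at 3")
  if (object@nK < 1L) return("nK must be >= 1")
  if (!identical(object@kernelSpatial, c(3L, 3L)))
    return("kernel spatial size is fixed at (3, 3)")
  if (!object@activation %in% c("linear", "relu"))
    return("activation must be linear or relu")
  TRUE
})

#' Construct a TemporalExtensionSpec
#' @param nK number of 3D kernels.
#' @param activation activation after the 3D convolution.
#' @param r temporal extent (must be 3).
#' @param kernelSpatial spatial kernel size (must be \code{c(3, 3)}).
#' @return A validated \linkS4class{TemporalExtensionSpec}.
#' @examples
#' TemporalExtensionSpec(nK = 3)
#' @export
TemporalExtensionSpec <- function(nK = 3L, activation = "relu", r = 3L,
                                  kernelSpatial = c(3L, 3L)) {
  new("TemporalExtensionSpec", r = as.integer(r), nK = as.integer(nK),
      kernelSpatial = as.integer(kernelSpatial), activation = activation)
}

#' EnsembleConfig: which members to fuse and how to binarize
#'
#' @slot members unique ordered subset of
#'   \code{c("m1", "m2", "M1", "M2")}; its length is the ensemble size k.
#' @slot binarizeThreshold numeric in \code{(0, 1)}.
#' @export
setClass("EnsembleConfig",
  representation(members = "character", binarizeThreshold = "numeric"))

setValidity("EnsembleConfig", function(object) {
  m <- object@members
  if (length(m) < 1L || length(m) > 4L) return("1 <= k <= 4 members")
  if (anyDuplicated(m)) return("members must be unique")
  if (!all(m %in% c("m1", "m2", "M1", "M2")))
    return("members must be drawn from m1, m2, M1, M2")
  th <- object@binarizeThreshold
  if (th <= 0 || th >= 1) return("binarizeThreshold must lie in (0, 1)")
  TRUE
})

#' Construct an EnsembleConfig
#' @param members character vector of member tags.
#' @param binarizeThreshold threshold applied to the fused map (default 0.5).
#' @return A validated \linkS4class{EnsembleConfig}.
#' @examples
#' EnsembleConfig(c("m1", "m2", "M1", "M2"))
#' @export
EnsembleConfig <- function(members = c("m1", "m2", "M1", "M2"),
                           binarizeThreshold = 0.5) {
  new("EnsembleConfig", members = as.character(members),
      binarizeThreshold = binarizeThreshold)
}

## ---------------------------------------------------------------------------
## Model handles
## ---------------------------------------------------------------------------

#' ResUNetModel: residual U-Net handle (weights + spec)
#'
#' @slot spec a \linkS4class{ResUNetSpec}.
#' @slot params nested list of weight arrays.
#' @slot trained logical.
#' @slot tag model tag used on emitted probability maps.
#' @export
setClass("ResUNetModel",
  representation(spec = "ResUNetSpec", params = "list", trained = "logical",
                 tag = "character"))

#' InstanceSegModel: proposal-based instance segmentation core handle
#'
#' @slot spec an \linkS4class{InstanceSegSpec}.
#' @slot params list of tunable parameters of the proposal generator
#'   (darkness quantiles, smoothing, minimum area fraction).
#' @slot trained logical.
#' @slot tag model tag.
#' @export
setClass("InstanceSegModel",
  representation(spec = "InstanceSegSpec", params = "list",
                 trained = "logical", tag = "character"))

#' ExtendedModel: a core model with a 3D-convolution temporal front
#'
#' @slot frontSpec a \linkS4class{TemporalExtensionSpec}.
#' @slot front list with the front's weight matrix \code{W}
#'   (\code{(r*3*3*n_c) x nK}) and bias \code{b}.
#' @slot core the wrapped core model (\linkS4class{ResUNetModel} or
#'   \linkS4class{InstanceSegModel}).
#' @slot tag model tag.
#' @export
setClass("ExtendedModel",
  representation(frontSpec = "TemporalExtensionSpec", front = "list",
                 core = "ANY", tag = "character"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "Frame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Frame %dx%dx%d  t=%d  video=%s  patient=%s\n",
              d[1L], d[2L], d[3L], object@t, object@videoId,
              object@patientId))
})

setMethod("show", "FrameTriplet", function(object) {
  d <- dim(object@frames[[1L]]@pixels)
  cat(sprintf("FrameTriplet center t=%d  %dx%d  boundary=%s  video=%s\n",
              object@centerIndex, d[1L], d[2L], object@boundaryFlag,
              object@frames[[1L]]@videoId))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %dx%d  t=%d  foreground=%d px\n",
              nrow(object@pixels), ncol(object@pixels), object@t,
              sum(object@pixels)))
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap %dx%d  t=%d  model=%s  mean=%.3f\n",
              nrow(object@pixels), ncol(object@pixels), object@t,
              object@modelTag, mean(object@pixels)))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts TP=%d FP=%d FN=%d TN=%d\n",
              object@tp, object@fp, object@fn, object@tn))
})

setMethod("show", "ResUNetModel", function(object) {
  s <- object@spec
  cat(sprintf(
    "ResUNetModel [%s]  depth=%d baseFilters=%d input=%dx%dx%d  %s\n",
    object@tag, s@depth, s@baseFilters, s@inputShape[1L], s@inputShape[2L],
    s@inputShape[3L], if (object@trained) "trained" else "untrained"))
  cat(sprintf("  parameters: %d\n", parameterCount(object)))
})

setMethod("show", "InstanceSegModel", function(object) {
  s <- object@spec
  cat(sprintf(
    "InstanceSegModel [%s]  backbone=%s conf=%.2f anchors=%s  %s\n",
    object@tag, s@backbone, s@minDetectionConfidence,
    paste(s@anchorScales, collapse = ","),
    if (object@trained) "trained" else "untrained"))
})

setMethod("show", "ExtendedModel", function(object) {
  fs <- object@frontSpec
  cat(sprintf("ExtendedModel [%s]  3D front: nK=%d act=%s  core: %s\n",
              object@tag, fs@nK, fs@activation, class(object@core)))
})

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' Pixel data of a frame, mask or probability map
#' @param x a \linkS4class{Frame}, \linkS4class{BinaryMask} or
#'   \linkS4class{ProbabilityMap}.
#' @return The underlying numeric array or matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
setMethod("pixels", "Frame", function(x) x@pixels)
#' @rdname pixels
setMethod("pixels", "BinaryMask", function(x) x@pixels)
#' @rdname pixels
setMethod("pixels", "ProbabilityMap", function(x) x@pixels)

#' Temporal index of a frame-like object
#' @param x a \linkS4class{Frame}, \linkS4class{FrameTriplet},
#'   \linkS4class{BinaryMask} or \linkS4class{ProbabilityMap}.
#' @return Integer frame index.
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' @rdname frameIndex
setMethod("frameIndex", "Frame", function(x) x@t)
#' @rdname frameIndex
setMethod("frameIndex", "FrameTriplet", function(x) x@centerIndex)
#' @rdname frameIndex
setMethod("frameIndex", "BinaryMask", function(x) x@t)
#' @rdname frameIndex
setMethod("frameIndex", "ProbabilityMap", function(x) x@t)

#' Ensemble members
#' @param x an \linkS4class{EnsembleConfig}.
#' @return Character vector of member tags.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname members
setMethod("members", "EnsembleConfig", function(x) x@members)
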