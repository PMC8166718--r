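#' Build the proposal-based instance segmentation core (m2)
#'
#' The second core model is a detector-style instance segmenter: it emits a
#' set of candidate instance masks with confidence scores which an adapter
#' (\code{\link{instancesToLumenMap}}) reduces to a single lumen probability
#' map. Here the proposal generator is classical: the frame's luminance is
#' smoothed, thresholded at a ladder of darkness quantiles (the lumen is the
#' least-illuminated region of the field of view), and connected components
#' become soft instance masks scored by their darkness contrast and
#' compactness. The spec's \code{minDetectionConfidence}, anchor scales and
#' backbone label form the configuration surface shared with detector-style
#' implementations; the anchor scales bound the plausible instance area and
#' the backbone label is accepted for configuration compatibility and does
#' not alter the classical proposal generator.
#'
#' @param spec an \linkS4class{InstanceSegSpec}.
#' @param params list of proposal tunables: \code{quantiles} (darkness
#'   quantile ladder), \code{sigma} (smoothing, px), \code{minAreaFrac}
#'   (minimum instance area as a fraction of the frame),
#'   \code{mergePolicy} (\code{"best"} or \code{"union"}).
#' @param tag model tag.
#' @return An \linkS4class{InstanceSegModel}.
#' @examples
#' m2 <- buildInstanceSegmenter()
#' @export
buildInstanceSegmenter <- function(spec = InstanceSegSpec(),
                                   params = list(), tag = "m2") {
  stopifnot(is(spec, "InstanceSegSpec"))
  validObject(spec)
  defaults <- list(quantiles = c(0.02, 0.05, 0.10, 0.18), sigma = 2,
                   minAreaFrac = 0.002, mergePolicy = "best")
  defaults[names(params)] <- params
  new("InstanceSegModel", spec = spec, params = defaults, trained = FALSE,
      tag = tag)
}

luminance <- function(px) {
  0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
}

# gblur whose brush never exceeds the image (small test frames)
safe_gblur <- function(x, sigma) {
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  lim <- min(dim(x)[1:2])
  if (r > lim) r <- lim - (1L - lim %% 2L)  # largest odd radius that fits
  EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = sigma,
                                    radius = r))
}

# Generate candidate instances for one frame: list(masks, scores).
# Soft masks are lightly smoothed component indicators in [0, 1]; scores are
# a logistic function of darkness contrast damped by compactness, in [0, 1].
propose_instances <- function(pixels, params, anchorScales) {
  gray <- luminance(pixels)
  sm <- safe_gblur(gray, params$sigma)
  p <- nrow(gray); q <- ncol(gray)
  minArea <- max(4, params$minAreaFrac * p * q)
  maxArea <- pi * (max(anchorScales) / 2)^2 * 4  # generous upper bound
  masks <- list(); scores <- numeric(0L)
  for (qt in params$quantiles) {
    thr <- stats::quantile(sm, qt, names = FALSE)
    lab <- EBImage::bwlabel(sm <= thr)
    nlab <- max(lab)
    if (nlab == 0L) next
    for (k in seq_len(nlab)) {
      comp <- lab == k
      area <- sum(comp)
      if (area < minArea || area > maxArea) next
      inside <- mean(sm[comp])
      outside <- mean(sm[!comp])
      contrast <- outside - inside
      idx <- which(comp, arr.ind = TRUE)
      cen <- colMeans(idx)
      rmax <- sqrt(max((idx[, 1L] - cen[1L])^2 + (idx[, 2L] - cen[2L])^2))
      compact <- min(1, area / (pi * max(rmax, 1)^2))
      soft <- pmin(pmax(safe_gblur(comp * 1, 1), 0), 1)
      masks[[length(masks) + 1L]] <- soft
      scores <- c(scores, stats::plogis(12 * (contrast - 0.05)) *
                    sqrt(max(compact, 0)))
    }
  }
  list(masks = masks, scores = scores)
}

#' Reduce instance detections to a single lumen probability map
#'
#' The adapter between an instance segmenter's output and the single-region
#' lumen map the ensemble consumes. Instances scoring below the confidence
#' threshold are discarded; of the survivors, \code{mergePolicy = "best"}
#' keeps the highest-scoring soft mask and \code{"union"} takes the
#' pixelwise maximum. With no survivors the map is all zero.
#'
#' @param instanceMasks list of \code{p x q} soft masks in \code{[0, 1]}.
#' @param scores numeric vector of scores in \code{[0, 1]}, one per mask.
#' @param confidenceThreshold minimal score to keep an instance.
#' @param mergePolicy \code{"best"} or \code{"union"}.
#' @param t,modelTag metadata for the returned map.
#' @return A \linkS4class{ProbabilityMap}.
#' @examples
#' m <- matrix(0, 16, 16); m[4:8, 4:8] <- 1
#' instancesToLumenMap(list(m), scores = 0.9, confidenceThreshold = 0.7)
#' @export
instancesToLumenMap <- function(instanceMasks, scores,
                                confidenceThreshold = 0.7,
                                mergePolicy = c("best", "union"),
                                t = 0L, modelTag = "m2") {
  mergePolicy <- match.arg(mergePolicy)
  if (length(instanceMasks) != length(scores))
    stop("instanceMasks and scores must have equal length")
  if (length(scores) && (any(scores < 0) || any(scores > 1)))
    stop("scores must lie in [0, 1]")
  keep <- which(scores >= confidenceThreshold)
  if (!length(keep)) {
    d <- if (length(instanceMasks)) dim(instanceMasks[[1L]]) else c(1L, 1L)
    return(ProbabilityMap(matrix(0, d[1L], d[2L]), t = t,
                          modelTag = modelTag))
  }
  if (mergePolicy == "best") {
    out <- instanceMasks[[keep[which.max(scores[keep])]]]
  } else {
    out <- instanceMasks[[keep[1L]]]
    for (k in keep[-1L]) out <- pmax(out, instanceMasks[[k]])
  }
  ProbabilityMap(out, t = t, modelTag = modelTag)
}

#' @rdname predictSingle
setMethod("predictSingle", c("InstanceSegModel", "Frame"),
  function(model, frame, ...) {
    pr <- propose_instances(frame@pixels, model@params,
                            model@spec@anchorScales)
    instancesToLumenMap(pr$masks, pr$scores,
                        confidenceThreshold = model@spec@minDetectionConfidence,
                        mergePolicy = model@params$mergePolicy,
                        t = frame@t, modelTag = model@tag)
  })

#' @describeIn buildInstanceSegmenter Tunable-parameter count of the proposal
#'   generator (quantile ladder, smoothing, area bound, confidence).
#' @param model an \linkS4class{InstanceSegModel}.
#' @export
setMethod("parameterCount", "InstanceSegModel",
  function(model)
    as.integer(length(model@params$quantiles) + 3L))
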