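#' Fuse member probability maps by arithmetic averaging
#'
#' The ensemble function: the fused prediction at every pixel is the
#' arithmetic mean of the k member predictions,
#' \deqn{F(p_i(t)) = \frac{1}{k} \sum_i^k p_i(t),}
#' with k taken as the number of supplied maps. Averaging operates on the
#' soft probability maps, not on pre-thresholded masks; the result is
#' permutation-invariant in member order and bounded pixelwise by the member
#' minimum and maximum.
#'
#' @param maps list of \linkS4class{ProbabilityMap}, all of the same shape
#'   and frame index.
#' @param modelTag tag for the fused map.
#' @return A \linkS4class{ProbabilityMap}.
#' @examples
#' a <- ProbabilityMap(matrix(1,  8, 8)); b <- ProbabilityMap(matrix(0, 8, 8))
#' mean(pixels(ensemblePredict(list(a, b, b, b))))  # 0.25
#' @export
ensemblePredict <- function(maps, modelTag = "ensemble") {
  if (!length(maps)) stop("input error: no maps supplied")
  stopifnot(all(vapply(maps, is, TRUE, "ProbabilityMap")))
  d <- dim(maps[[1L]]@pixels)
  tt <- maps[[1L]]@t
  for (m in maps[-1L]) {
    if (!all(dim(m@pixels) == d))
      stop("alignment error: member maps differ in shape")
    if (m@t != tt)
      stop("alignment error: member maps index different frames")
  }
  acc <- Reduce(`+`, lapply(maps, slot, "pixels"))
  ProbabilityMap(acc / length(maps), t = tt, modelTag = modelTag)
}

#' Threshold a probability map into a binary mask
#'
#' A pixel becomes foreground iff its probability is greater than or equal
#' to the threshold.
#'
#' @param map a \linkS4class{ProbabilityMap}.
#' @param threshold numeric in \code{(0, 1)}; default 0.5, the natural
#'   decision boundary for a mean of probabilities.
#' @param videoId metadata for the returned mask.
#' @return A \linkS4class{BinaryMask}.
#' @export
binarize <- function(map, threshold = 0.5, videoId = "pred") {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("config error: threshold must lie in (0, 1)")
  px <- if (is(map, "ProbabilityMap")) map@pixels else map
  BinaryMask((px >= threshold) * 1,
             t = if (is(map, "ProbabilityMap")) map@t else 0L,
             videoId = videoId)
}

#' Select the binarization threshold on validation data
#'
#' Operating-point calibration: sweeps a threshold grid and returns the
#' value maximizing mean per-frame DSC of the supplied probability maps
#' against their reference masks (ties broken toward 0.5). Meant to be run
#' on validation predictions, mirroring the confidence sweep of the
#' instance core; the chosen value feeds \code{\link{binarize}} /
#' \code{EnsembleConfig(binarizeThreshold = )}.
#'
#' @param maps list of \linkS4class{ProbabilityMap}.
#' @param masks parallel list of reference \linkS4class{BinaryMask}.
#' @param grid candidate thresholds in \code{(0, 1)}.
#' @return list with \code{threshold} and the sweep \code{table}.
#' @export
selectThreshold <- function(maps, masks,
                            grid = seq(0.25, 0.7, by = 0.05)) {
  stopifnot(length(maps) == length(masks), length(maps) > 0)
  dscs <- vapply(grid, function(th) {
    mean(vapply(seq_along(maps), function(i)
      dsc(confusionCounts(binarize(maps[[i]], th),
                          masks[[i]]@pixels)), 0))
  }, 0)
  best <- which(dscs >= max(dscs) - 1e-12)
  pick <- best[which.min(abs(grid[best] - 0.5))]
  list(threshold = grid[pick],
       table = data.frame(threshold = grid, dsc = dscs))
}

#' Run an ensemble configuration on one frame/triplet
#'
#' Dispatches each configured member model on the appropriate input (cores
#' on the central frame, extended models on the triplet), fuses the member
#' maps with \code{\link{ensemblePredict}} and returns both the fused soft
#' map and its binarization. Any subset of \{m1, m2, M1, M2\} runs through
#' this same code path, so the ablation pairs and the full 4-member
#' ensemble are all expressible via the config.
#'
#' @param models named list of model handles keyed by member tag.
#' @param config an \linkS4class{EnsembleConfig}.
#' @param triplet a \linkS4class{FrameTriplet}; single-frame members use its
#'   central frame.
#' @return list with \code{map} (\linkS4class{ProbabilityMap}),
#'   \code{mask} (\linkS4class{BinaryMask}) and \code{memberMaps}.
#' @export
ensembleSegment <- function(models, config, triplet) {
  validObject(config)
  missing <- setdiff(config@members, names(models))
  if (length(missing))
    stop("dependency error: no model supplied for member(s) ",
         paste(missing, collapse = ", "))
  center <- triplet@frames[[2L]]
  memberMaps <- lapply(config@members, function(tag) {
    m <- models[[tag]]
    if (is(m, "ExtendedModel")) predictTriplet(m, triplet)
    else predictSingle(m, center)
  })
  names(memberMaps) <- config@members
  fused <- ensemblePredict(memberMaps)
  list(map = fused,
       mask = binarize(fused, config@binarizeThreshold,
                       videoId = center@videoId),
       memberMaps = memberMaps)
}
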