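#' Sample one set of augmentation parameters
#'
#' Draws a quarter-turn rotation uniformly from \{0, 1, 2, 3\}, fair
#' horizontal and vertical flips, and a zoom factor uniform on
#' \code{[0.98, 1.02]} (zooming in and out within two percent of the
#' original size). Deterministic for a fixed seed. Augmentation is applied
#' offline, before training.
#'
#' @param seed integer seed.
#' @return An \linkS4class{AugmentationParams}.
#' @examples
#' identical(sampleAugmentation(7), sampleAugmentation(7))
#' @export
sampleAugmentation <- function(seed) {
  with_seed(seed, {
    AugmentationParams(
      rotationQuarterTurns = sample(0:3, 1L),
      hflip = stats::runif(1L) < 0.5,
      vflip = stats::runif(1L) < 0.5,
      zoomFactor = stats::runif(1L, 0.98, 1.02),
      seed = seed)
  })
}

# One quarter turn: out[i, j] = in[j, p - i + 1] (dims swap for non-square).
rot90_mat <- function(m) t(m[nrow(m):1L, , drop = FALSE])

apply_geom <- function(arr, params, isMask) {
  is3d <- length(dim(arr)) == 3L
  p <- dim(arr)[1L]; q <- dim(arr)[2L]
  z <- params@zoomFactor
  if (z != 1) {
    np <- max(1L, round(p * z)); nq <- max(1L, round(q * z))
    arr <- if (isMask) resize_nearest(arr, np, nq)
           else resize_bilinear(arr, np, nq)
    if (np >= p) {  # zoom in: center crop
      i0 <- (np - p) %/% 2L; j0 <- (nq - q) %/% 2L
      arr <- if (is3d) arr[i0 + seq_len(p), j0 + seq_len(q), , drop = FALSE]
             else arr[i0 + seq_len(p), j0 + seq_len(q), drop = FALSE]
    } else {        # zoom out: zero pad
      out <- if (is3d) array(0, c(p, q, dim(arr)[3L])) else matrix(0, p, q)
      i0 <- (p - np) %/% 2L; j0 <- (q - nq) %/% 2L
      if (is3d) out[i0 + seq_len(np), j0 + seq_len(nq), ] <- arr
      else out[i0 + seq_len(np), j0 + seq_len(nq)] <- arr
      arr <- out
    }
  }
  per_plane <- function(f, a) {
    if (length(dim(a)) == 2L) return(f(a))
    planes <- lapply(seq_len(dim(a)[3L]), function(k) f(a[, , k]))
    array(unlist(planes), c(dim(planes[[1L]]), length(planes)))
  }
  k <- params@rotationQuarterTurns
  if (k > 0L) for (i in seq_len(k)) arr <- per_plane(rot90_mat, arr)
  if (params@hflip)
    arr <- per_plane(function(m) m[nrow(m):1L, , drop = FALSE], arr)
  if (params@vflip)
    arr <- per_plane(function(m) m[, ncol(m):1L, drop = FALSE], arr)
  arr
}

#' Apply one augmentation jointly to an image and its mask
#'
#' The same geometric map (zoom about the center, quarter-turn rotation,
#' flips) is applied to the image -- or to all three frames of a triplet,
#' preserving temporal coherence -- and to the mask. Images are resampled
#' bilinearly; masks use nearest-neighbour so they stay binary. Zoom-in
#' center-crops and zoom-out zero-pads back to the original size, so output
#' spatial dims equal input dims; quarter-turn rotations of non-square
#' inputs swap p and q, identically for image and mask. The identity
#' parameters (0 turns, no flips, zoom 1) reproduce both inputs bitwise.
#'
#' @param image a \linkS4class{Frame} or \linkS4class{FrameTriplet}.
#' @param mask the aligned \linkS4class{BinaryMask}.
#' @param params an \linkS4class{AugmentationParams}.
#' @return list with \code{image} (same class as the input) and \code{mask}.
#' @export
applyAugmentation <- function(image, mask, params) {
  validObject(params)
  msk <- if (is(mask, "BinaryMask")) mask@pixels else mask
  ref <- if (is(image, "FrameTriplet")) image@frames[[1L]]@pixels
         else image@pixels
  if (!all(dim(ref)[1:2] == dim(msk)))
    stop("alignment error: image and mask spatial dims differ")
  transform_frame <- function(fr) {
    fr@pixels <- pmin(pmax(apply_geom(fr@pixels, params, isMask = FALSE),
                           0), 1)
    fr
  }
  out_image <- if (is(image, "FrameTriplet")) {
    image@frames <- lapply(image@frames, transform_frame)
    image
  } else transform_frame(image)
  newMask <- apply_geom(msk, params, isMask = TRUE)
  newMask <- (newMask >= 0.5) * 1
  out_mask <- if (is(mask, "BinaryMask")) {
    mask@pixels <- newMask; mask
  } else newMask
  list(image = out_image, mask = out_mask)
}

#' Augment a dataset offline
#'
#' Appends \code{copiesPerFrame} augmented copies of every frame/mask pair
#' to a dataset, each drawn from an independent sub-seed of \code{seed}.
#' Copies inherit the source frame's \code{patientId} and \code{videoId} so
#' patient-wise folds remain leak-free.
#'
#' @param dataset list with parallel \code{frames} and \code{masks} lists
#'   (and optionally a \code{manifest} data.frame).
#' @param copiesPerFrame augmented copies per original (default 4).
#' @param seed master seed.
#' @return The enlarged dataset; added manifest rows carry
#'   \code{augmented = TRUE}.
#' @export
augmentDataset <- function(dataset, copiesPerFrame = 4L, seed = 1L) {
  n <- length(dataset$frames)
  newF <- list(); newM <- list()
  rows <- NULL
  for (i in seq_len(n)) {
    for (cpy in seq_len(copiesPerFrame)) {
      pars <- sampleAugmentation(derive_seed(seed, (i - 1L) * copiesPerFrame +
                                               cpy))
      aug <- applyAugmentation(dataset$frames[[i]], dataset$masks[[i]], pars)
      newF[[length(newF) + 1L]] <- aug$image
      newM[[length(newM) + 1L]] <- aug$mask
      rows <- rbind(rows, data.frame(
        videoId = aug$image@videoId, patientId = aug$image@patientId,
        t = aug$image@t, augmented = TRUE))
    }
  }
  out <- dataset
  out$frames <- c(dataset$frames, newF)
  out$masks <- c(dataset$masks, newM)
  if (!is.null(dataset$manifest)) {
    man <- dataset$manifest
    man$augmented <- FALSE
    keep <- intersect(names(man), names(rows))
    out$manifest <- rbind(man[, c(keep, setdiff(names(man), keep))],
                          cbind(rows[, keep],
                                as.data.frame(
                                  setNames(
                                    rep(list(NA), length(setdiff(names(man),
                                                                 keep))),
                                    setdiff(names(man), keep)))))
  }
  out
}
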