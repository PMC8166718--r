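#' Read an ordered frame sequence from a directory
#'
#' Reads every decodable PNG/JPEG in a directory as one video's frames,
#' normalized to \code{[0, 1]} (8-bit images are divided by 255 by the
#' decoder). Frames are ordered by the numeric part of their filename stems
#' (zero-padding-safe); stems without digits fall back to lexicographic
#' order. All frames of one video must share spatial dimensions; videos may
#' differ from each other (sizes are unified later by the training
#' pipeline's resizing, not at read time).
#'
#' @param path directory containing the frames. Video containers (mp4/avi)
#'   are not decodable here and raise an informative error; extract frames
#'   to a directory first.
#' @param videoId,patientId provenance attached to every frame.
#' @param pattern filename regexp for frame images.
#' @return list of \linkS4class{Frame}, \code{t = 0 .. n-1}.
#' @export
readFrameSequence <- function(path, videoId = basename(path),
                              patientId = "unknown",
                              pattern = "\\.(png|jpe?g)$") {
  if (!file.exists(path))
    stop("input error: path does not exist: ", path)
  if (!dir.exists(path)) {
    if (grepl("\\.(mp4|avi|mov|mkv)$", path, ignore.case = TRUE))
      stop("video containers are not decodable in this build; extract ",
           "frames to a PNG/JPEG directory first")
    stop("input error: path is not a directory: ", path)
  }
  files <- list.files(path, pattern = pattern, ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[!grepl("_mask\\.", basename(files))]
  if (!length(files))
    stop("empty-sequence error: no decodable frames under ", path)
  stems <- sub("\\.[^.]+$", "", basename(files))
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", stems)))
  files <- if (all(is.finite(num))) files[order(num, stems)]
           else files[order(stems)]
  frames <- vector("list", length(files))
  dims <- NULL
  for (i in seq_along(files)) {
    px <- EBImage::imageData(EBImage::readImage(files[i]))
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
    if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
    px <- pmin(pmax(px, 0), 1)
    if (is.null(dims)) dims <- dim(px)[1:2]
    else if (!all(dim(px)[1:2] == dims))
      stop("format error: inconsistent spatial sizes within one sequence (",
           paste(dims, collapse = "x"), " vs ",
           paste(dim(px)[1:2], collapse = "x"), ")")
    frames[[i]] <- Frame(px, t = i - 1L, videoId = videoId,
                         patientId = patientId)
  }
  frames
}

#' Assemble ordered frame triplets from a frame sequence
#'
#' Forms the \code{(I(t-1), I(t), I(t+1))} inputs of the multi-frame models.
#' With \code{"replicate_edge"} the first and last frames are replicated so
#' every frame is a triplet center (output length equals input length); with
#' \code{"drop_edges"} only interior frames become centers (length
#' \code{max(0, n-2)}).
#'
#' @param frames ordered list of \linkS4class{Frame} from one video.
#' @param boundaryPolicy \code{"replicate_edge"} (default) or
#'   \code{"drop_edges"}.
#' @return list of \linkS4class{FrameTriplet}.
#' @examples
#' fr <- lapply(0:4, function(t) Frame(array(0.5, c(8, 8, 3)), t = t))
#' length(makeTriplets(fr))                 # 5
#' length(makeTriplets(fr, "drop_edges"))   # 3
#' @export
makeTriplets <- function(frames,
                         boundaryPolicy = c("replicate_edge", "drop_edges")) {
  boundaryPolicy <- match.arg(boundaryPolicy)
  n <- length(frames)
  if (n == 0L) stop("empty-sequence error: no frames supplied")
  mk <- function(a, b, c, flag)
    new("FrameTriplet", frames = list(a, b, c),
        centerIndex = b@t, boundaryFlag = flag)
  if (boundaryPolicy == "drop_edges") {
    if (n < 3L) return(list())
    return(lapply(2:(n - 1L), function(i)
      mk(frames[[i - 1L]], frames[[i]], frames[[i + 1L]], "interior")))
  }
  lapply(seq_len(n), function(i) {
    if (i == 1L)
      mk(frames[[1L]], frames[[1L]], frames[[min(2L, n)]], "replicated_left")
    else if (i == n)
      mk(frames[[n - 1L]], frames[[n]], frames[[n]], "replicated_right")
    else
      mk(frames[[i - 1L]], frames[[i]], frames[[i + 1L]], "interior")
  })
}

#' Write a binary mask as a lossless PNG
#'
#' Foreground is written as 255 and background as 0; reading the file back
#' with \code{\link{readMask}} reproduces the mask exactly.
#'
#' @param mask a \linkS4class{BinaryMask}, or a 0/1 matrix.
#' @param path output PNG path.
#' @return invisibly, the path.
#' @export
writeMask <- function(mask, path) {
  if (is.matrix(mask)) mask <- BinaryMask(mask)
  validObject(mask)
  if (!dir.exists(dirname(path)))
    stop("I/O error: directory does not exist: ", dirname(path))
  EBImage::writeImage(EBImage::Image(mask@pixels), path, type = "png")
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path PNG file with foreground > 127 (e.g. 255) and background 0.
#' @param t,videoId metadata for the returned mask.
#' @return A \linkS4class{BinaryMask}.
#' @export
readMask <- function(path, t = 0L, videoId = "v1") {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  px <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  BinaryMask((px >= 0.5) * 1, t = t, videoId = videoId)
}

#' Read the ground-truth masks matching a frame sequence
#'
#' Masks follow the \code{<frame_stem>_mask.png} filename convention in the
#' same directory as the frames.
#'
#' @param path frame directory.
#' @param frames the frames returned by \code{\link{readFrameSequence}}
#'   (used only for count/order checking); may be \code{NULL}.
#' @param videoId video identifier for the masks.
#' @return list of \linkS4class{BinaryMask} in frame order.
#' @export
readMaskSequence <- function(path, frames = NULL, videoId = basename(path)) {
  files <- list.files(path, pattern = "_mask\\.png$", full.names = TRUE)
  if (!length(files)) stop("empty-sequence error: no masks under ", path)
  stems <- sub("_mask\\.png$", "", basename(files))
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", stems)))
  files <- if (all(is.finite(num))) files[order(num, stems)]
           else files[order(stems)]
  masks <- lapply(seq_along(files), function(i)
    readMask(files[i], t = i - 1L, videoId = videoId))
  if (!is.null(frames) && length(masks) != length(frames))
    stop("format error: ", length(masks), " masks for ", length(frames),
         " frames")
  masks
}
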