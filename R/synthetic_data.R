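#' SyntheticSceneParams: generative parameters for a synthetic
#' ureteroscopy video
#'
#' The generator emulates the statistical structure of ureteroscopic video:
#' a dark, roughly elliptical lumen (the least-illuminated region of the
#' field of view) drifting smoothly across frames over a brighter reddish
#' textured wall with radial illumination falloff, plus the common artifact
#' taxonomy -- specular highlights, floating debris, blur, bleeding tint,
#' and optional full-frame corruption of isolated center frames (which
#' exercises temporal recovery, the multi-frame models' motivating
#' scenario). Ground-truth masks are the exact ellipse interior.
#'
#' @slot frameSize integer(2) \code{c(p, q)}.
#' @slot nFrames integer >= 1.
#' @slot lumenCenterAmplitude numeric, drift amplitude in pixels.
#' @slot lumenAngularSpeed numeric, drift angular speed (rad/frame).
#' @slot lumenRadii numeric(2) ellipse semi-axes (a, b) in pixels.
#' @slot radiusJitter numeric, relative smooth per-frame radius modulation.
#' @slot wallTextureScale numeric, amplitude of the wall texture.
#' @slot illuminationFalloff numeric in \code{[0, 1)}, depth of the radial
#'   darkening around the lumen.
#' @slot artifactRates named numeric: per-frame probabilities for
#'   \code{specularity}, \code{debris}, \code{blur}, \code{bleeding_tint},
#'   \code{center_frame_corruption}.
#' @slot noiseSigma numeric, per-pixel Gaussian noise sd.
#' @slot seed integer.
#' @export
setClass("SyntheticSceneParams",
  representation(frameSize = "integer", nFrames = "integer",
                 lumenCenterAmplitude = "numeric",
                 lumenAngularSpeed = "numeric", lumenRadii = "numeric",
                 radiusJitter = "numeric", wallTextureScale = "numeric",
                 illuminationFalloff = "numeric", artifactRates = "numeric",
                 noiseSigma = "numeric", seed = "integer"))

setValidity("SyntheticSceneParams", function(object) {
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (any(object@artifactRates < 0) || any(object@artifactRates > 1))
    return("artifact rates must be probabilities in [0, 1]")
  if (max(object@lumenRadii) >= min(object@frameSize) / 2)
    return("lumen radii must be smaller than half the frame")
  if (object@illuminationFalloff < 0 || object@illuminationFalloff >= 1)
    return("illuminationFalloff must lie in [0, 1)")
  req <- c("specularity", "debris", "blur", "bleeding_tint",
           "center_frame_corruption")
  if (!all(req %in% names(object@artifactRates)))
    return("artifactRates must name all five artifact classes")
  TRUE
})

#' Construct SyntheticSceneParams
#'
#' Defaults describe the package's standard desk-scale fixture: 64 x 64
#' frames, a lumen of semi-axes (10, 8) px drifting with amplitude 9 px,
#' moderate wall texture and illumination falloff, and light artifact rates.
#'
#' @param frameSize,nFrames,lumenCenterAmplitude,lumenAngularSpeed see slots.
#' @param lumenRadii,radiusJitter,wallTextureScale,illuminationFalloff idem.
#' @param artifactRates,noiseSigma,seed idem.
#' @return A validated \linkS4class{SyntheticSceneParams}.
#' @examples
#' SyntheticSceneParams(nFrames = 10)
#' @export
SyntheticSceneParams <- function(frameSize = c(64L, 64L), nFrames = 40L,
    lumenCenterAmplitude = 9, lumenAngularSpeed = 0.15,
    lumenRadii = c(10, 8), radiusJitter = 0.06, wallTextureScale = 0.12,
    illuminationFalloff = 0.55,
    artifactRates = c(specularity = 0.25, debris = 0.15, blur = 0.10,
                      bleeding_tint = 0.10, center_frame_corruption = 0),
    noiseSigma = 0.02, seed = 1L) {
  new("SyntheticSceneParams", frameSize = as.integer(frameSize),
      nFrames = as.integer(nFrames),
      lumenCenterAmplitude = lumenCenterAmplitude,
      lumenAngularSpeed = lumenAngularSpeed, lumenRadii = lumenRadii,
      radiusJitter = radiusJitter, wallTextureScale = wallTextureScale,
      illuminationFalloff = illuminationFalloff,
      artifactRates = artifactRates, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

add_blob <- function(px, cx, cy, r, color, alpha) {
  p <- dim(px)[1L]; q <- dim(px)[2L]
  xs <- seq_len(p); ys <- seq_len(q)
  g <- exp(-(outer((xs - cx)^2, (ys - cy)^2, "+")) / (2 * r^2)) * alpha
  for (ch in 1:3) px[, , ch] <- px[, , ch] * (1 - g) + color[ch] * g
  px
}

#' Generate one synthetic ureteroscopy video with exact masks
#'
#' Deterministic for a fixed \code{params@seed}. In every clean
#' (uncorrupted) frame the mean intensity inside the lumen mask is strictly
#' below the mean outside, so the segmentation task is learnable by
#' construction; the mask centroid follows a smooth trajectory so
#' consecutive frames differ minimally. Corrupted center frames (full-frame
#' noise) are never adjacent, keeping their temporal neighbours clean.
#'
#' @param params a \linkS4class{SyntheticSceneParams}.
#' @param videoId,patientId provenance for the emitted frames.
#' @return list with \code{frames} (list of \linkS4class{Frame}),
#'   \code{masks} (list of \linkS4class{BinaryMask}) and \code{artifacts}
#'   (per-frame flag data.frame).
#' @examples
#' v <- generateVideo(SyntheticSceneParams(nFrames = 3, seed = 7))
#' length(v$frames)
#' @export
generateVideo <- function(params, videoId = "v1", patientId = "p1") {
  validObject(params)
  p <- params@frameSize[1L]; q <- params@frameSize[2L]
  n <- params@nFrames
  rates <- params@artifactRates
  with_seed(params@seed, {
    base <- c(stats::runif(1, 0.55, 0.75), stats::runif(1, 0.30, 0.45),
              stats::runif(1, 0.22, 0.38))
    ntex <- 5L
    ta <- stats::runif(ntex, 0.3, 1)
    tfx <- stats::runif(ntex, 0.02, 0.09)
    tfy <- stats::runif(ntex, 0.02, 0.09)
    tph <- stats::runif(ntex, 0, 2 * pi)
    ph0 <- stats::runif(1, 0, 2 * pi)
    ph1 <- stats::runif(1, 0, 2 * pi)
    pha <- stats::runif(1, 0, 2 * pi)
    xs <- seq_len(p); ys <- seq_len(q)
    tex <- matrix(0, p, q)
    for (k in seq_len(ntex))
      tex <- tex + ta[k] *
        sin(2 * pi * (outer(tfx[k] * xs, tfy[k] * ys, "+")) + tph[k])
    tex <- tex / ntex
    frames <- vector("list", n)
    masks <- vector("list", n)
    art <- data.frame(t = seq_len(n) - 1L, specularity = FALSE,
                      debris = FALSE, blur = FALSE, bleeding_tint = FALSE,
                      corrupted = FALSE)
    prevCorrupt <- TRUE  # frame 0 is never corrupted -> neighbours clean
    w <- params@lumenAngularSpeed
    for (t0 in seq_len(n) - 1L) {
      cx <- p / 2 + params@lumenCenterAmplitude * cos(w * t0 + ph0)
      cy <- q / 2 + params@lumenCenterAmplitude * sin(0.7 * w * t0 + ph1)
      a <- params@lumenRadii[1L] * (1 + params@radiusJitter *
                                      sin(0.31 * t0 + pha))
      b <- params@lumenRadii[2L] * (1 + params@radiusJitter *
                                      cos(0.27 * t0 + pha))
      rho2 <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, "+")
      mask <- (rho2 <= 1) * 1
      d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
      sigL <- 2 * max(a, b)
      illum <- 1 - params@illuminationFalloff * exp(-d2 / (2 * sigL^2))
      shade <- illum * (1 + params@wallTextureScale * tex)
      px <- array(0, c(p, q, 3L))
      for (ch in 1:3) px[, , ch] <- base[ch] * shade
      inside <- mask == 1
      lum_fac <- 0.08 + 0.10 * sqrt(pmin(rho2, 1))
      for (ch in 1:3) {
        pl <- px[, , ch]
        pl[inside] <- (base[ch] * lum_fac)[inside]
        px[, , ch] <- pl
      }
      # artifacts
      if (stats::runif(1) < rates[["specularity"]]) {
        art$specularity[t0 + 1L] <- TRUE
        for (s in seq_len(sample(1:3, 1L))) {
          for (try in 1:20) {
            sx <- stats::runif(1, 2, p - 1); sy <- stats::runif(1, 2, q - 1)
            if (((sx - cx) / a)^2 + ((sy - cy) / b)^2 > 1.4) break
          }
          px <- add_blob(px, sx, sy, stats::runif(1, 1, 2.5), c(1, 1, 1),
                         0.95)
        }
      }
      if (stats::runif(1) < rates[["debris"]]) {
        art$debris[t0 + 1L] <- TRUE
        px <- add_blob(px, stats::runif(1, 1, p), stats::runif(1, 1, q),
                       stats::runif(1, 2, 5), c(0.35, 0.25, 0.15),
                       stats::runif(1, 0.35, 0.6))
      }
      if (stats::runif(1) < rates[["bleeding_tint"]]) {
        art$bleeding_tint[t0 + 1L] <- TRUE
        px[, , 1L] <- px[, , 1L] + 0.25 * (1 - px[, , 1L])
        px[, , 2L] <- px[, , 2L] * 0.75
        px[, , 3L] <- px[, , 3L] * 0.75
      }
      if (stats::runif(1) < rates[["blur"]]) {
        art$blur[t0 + 1L] <- TRUE
        px <- EBImage::imageData(EBImage::gblur(
          EBImage::Image(px, colormode = "Color"), sigma = 1.2))
      }
      if (params@noiseSigma > 0)
        px <- px + array(stats::rnorm(p * q * 3L, sd = params@noiseSigma),
                         c(p, q, 3L))
      doCorrupt <- stats::runif(1) < rates[["center_frame_corruption"]]
      if (doCorrupt && !prevCorrupt && t0 > 0L && t0 < n - 1L) {
        art$corrupted[t0 + 1L] <- TRUE
        px <- array(stats::runif(p * q * 3L), c(p, q, 3L))
        prevCorrupt <- TRUE
      } else prevCorrupt <- FALSE
      px <- pmin(pmax(px, 0), 1)
      frames[[t0 + 1L]] <- Frame(px, t = t0, videoId = videoId,
                                 patientId = patientId)
      masks[[t0 + 1L]] <- BinaryMask(mask, t = t0, videoId = videoId)
    }
    list(frames = frames, masks = masks, artifacts = art)
  })
}

#' Generate a multi-patient synthetic dataset
#'
#' Produces \code{nVideos} videos grouped into synthetic patients. With the
#' default 11 videos the grouping mirrors a realistic clinical collection --
#' 6 patients holding 2, 2, 1, 1, 1 and 4 videos -- so at least one patient
#' contributes multiple videos. Each video draws its own wall hue, lumen
#' radii scale and artifact-rate jitter from a per-video sub-seed of
#' \code{seed} (counter-based, so a video's content does not depend on
#' generation order). A manifest lists every frame with its mask, video,
#' patient, temporal index and artifact flags.
#'
#' @param nVideos number of videos (default 11).
#' @param framesPerVideo frames per video (default 40).
#' @param template a \linkS4class{SyntheticSceneParams} used as the base for
#'   every video.
#' @param seed master seed.
#' @param dir optional directory; when given, frames and masks are written
#'   as PNG (\code{<stem>.png} / \code{<stem>_mask.png}) per video plus a
#'   \code{manifest.csv}, the same layout \code{\link{readFrameSequence}}
#'   reads.
#' @return list with \code{frames}, \code{masks}, \code{manifest}.
#' @examples
#' ds <- generateDataset(nVideos = 2, framesPerVideo = 3,
#'                       template = SyntheticSceneParams(frameSize = c(32, 32),
#'                                                       lumenRadii = c(6, 5)),
#'                       seed = 1)
#' nrow(ds$manifest)
#' @export
generateDataset <- function(nVideos = 11L, framesPerVideo = 40L,
                            template = SyntheticSceneParams(), seed = 1L,
                            dir = NULL) {
  if (nVideos < 1L) stop("config error: nVideos must be >= 1")
  patientOf <- if (nVideos == 11L) c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 6L, 6L,
                                     6L, 6L)
  else sort(rep(seq_len(max(1L, ceiling(nVideos / 2))),
                length.out = nVideos))
  frames <- list(); masks <- list(); manifest <- NULL
  for (v in seq_len(nVideos)) {
    sv <- derive_seed(seed, v)
    vary <- with_seed(sv, list(
      rscale = stats::runif(1, 0.85, 1.2),
      amp = stats::runif(1, 0.7, 1.15),
      rjit = stats::runif(length(template@artifactRates), 0.6, 1.4)))
    pv <- template
    pv@nFrames <- as.integer(framesPerVideo)
    pv@lumenRadii <- template@lumenRadii * vary$rscale
    pv@lumenCenterAmplitude <- template@lumenCenterAmplitude * vary$amp
    pv@artifactRates <- pmin(template@artifactRates * vary$rjit, 1)
    # corruption is an experimental switch, not jittered
    pv@artifactRates[["center_frame_corruption"]] <-
      template@artifactRates[["center_frame_corruption"]]
    pv@seed <- derive_seed(sv, 1L)
    vid <- sprintf("video%02d", v)
    pat <- sprintf("patient%d", patientOf[v])
    out <- generateVideo(pv, videoId = vid, patientId = pat)
    frames <- c(frames, out$frames)
    masks <- c(masks, out$masks)
    man <- cbind(data.frame(videoId = vid, patientId = pat,
                            t = out$artifacts$t),
                 out$artifacts[, -1L])
    manifest <- rbind(manifest, man)
    if (!is.null(dir)) {
      vdir <- file.path(dir, vid)
      dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(out$frames)) {
        stem <- sprintf("f%04d", i - 1L)
        EBImage::writeImage(
          EBImage::Image(out$frames[[i]]@pixels, colormode = "Color"),
          file.path(vdir, paste0(stem, ".png")), type = "png")
        writeMask(out$masks[[i]], file.path(vdir, paste0(stem,
                                                         "_mask.png")))
      }
    }
  }
  manifest$frame <- file.path(manifest$videoId,
                              sprintf("f%04d.png", manifest$t))
  manifest$mask <- file.path(manifest$videoId,
                             sprintf("f%04d_mask.png", manifest$t))
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(frames = frames, masks = masks, manifest = manifest)
}

#' Patient-wise train/test split of a dataset
#'
#' All frames of the held-out patient(s) form the test set; no patient
#' appears on both sides.
#'
#' @param dataset as returned by \code{\link{generateDataset}}.
#' @param heldOutPatients character vector of patient ids to hold out.
#' @return list with \code{train} and \code{test} datasets.
#' @export
splitByPatient <- function(dataset, heldOutPatients) {
  pid <- vapply(dataset$frames, function(f) f@patientId, "")
  te <- pid %in% heldOutPatients
  subset_ds <- function(keep) list(
    frames = dataset$frames[keep], masks = dataset$masks[keep],
    manifest = if (!is.null(dataset$manifest)) dataset$manifest[keep, ,
                                                                drop = FALSE])
  list(train = subset_ds(!te), test = subset_ds(te))
}
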