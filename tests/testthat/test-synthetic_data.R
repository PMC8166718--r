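clean_params <- function(...) {
  SyntheticSceneParams(
    artifactRates = c(specularity = 0, debris = 0, blur = 0,
                      bleeding_tint = 0, center_frame_corruption = 0),
    noiseSigma = 0, ...)
}

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generateVideo(SyntheticSceneParams(nFrames = 8L, seed = 31))
  b <- generateVideo(SyntheticSceneParams(nFrames = 8L, seed = 31))
  for (i in 1:8) {
    expect_identical(pixels(a$frames[[i]]), pixels(b$frames[[i]]))
    expect_identical(pixels(a$masks[[i]]), pixels(b$masks[[i]]))
  }
  c2 <- generateVideo(SyntheticSceneParams(nFrames = 8L, seed = 32))
  expect_false(identical(pixels(a$frames[[1]]), pixels(c2$frames[[1]])))
})

test_that("the lumen is the illumination minimum of every clean frame", {
  v <- generateVideo(clean_params(nFrames = 6L, seed = 7))
  for (i in 1:6) {
    lum <- apply(pixels(v$frames[[i]]), c(1, 2), mean)
    msk <- pixels(v$masks[[i]])
    expect_lt(mean(lum[msk == 1]), mean(lum[msk == 0]))
    # the darkest 1% of pixels lie inside the mask
    thr <- quantile(lum, 0.01)
    expect_true(all(msk[lum <= thr] == 1))
  }
})

test_that("mask area matches the ellipse closed form", {
  v <- generateVideo(clean_params(frameSize = c(128L, 128L),
                                  lumenRadii = c(16, 12),
                                  radiusJitter = 0, nFrames = 3L,
                                  seed = 13))
  for (i in 1:3) {
    frac <- mean(pixels(v$masks[[i]]))
    expect_lt(abs(frac - pi * 16 * 12 / 128^2), 0.003)
  }
})

test_that("the mask centroid drifts smoothly between frames", {
  v <- generateVideo(clean_params(nFrames = 12L, seed = 17))
  cen <- t(vapply(v$masks, function(m) {
    idx <- which(pixels(m) == 1, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))
  step <- sqrt(rowSums(diff(cen)^2))
  # amplitude 9 px at angular speed 0.15 rad/frame: |dc/dt| <= ~1.4 px,
  # allow rasterization slack
  expect_true(all(step < 3))
})

test_that("center-frame corruption spares its temporal neighbours", {
  v <- generateVideo(SyntheticSceneParams(
    nFrames = 40L,
    artifactRates = c(specularity = 0, debris = 0, blur = 0,
                      bleeding_tint = 0, center_frame_corruption = 0.5),
    noiseSigma = 0, seed = 23))
  flags <- v$artifacts$corrupted
  expect_gt(sum(flags), 0)
  expect_false(flags[1])
  expect_false(flags[40])
  expect_true(all(!(flags[-1] & flags[-40])))  # never adjacent
  # a corrupted frame no longer separates lumen from wall
  i <- which(flags)[1]
  lum <- apply(pixels(v$frames[[i]]), c(1, 2), mean)
  msk <- pixels(v$masks[[i]])
  expect_gt(mean(lum[msk == 1]), 0.3)
})

test_that("dataset structure mirrors a multi-video patient collection", {
  ds <- generateDataset(nVideos = 11, framesPerVideo = 2,
                        template = tiny_scene(), seed = 3)
  expect_length(ds$frames, 22L)
  expect_identical(length(unique(ds$manifest$patientId)), 6L)
  perPatient <- table(unique(ds$manifest[c("videoId",
                                           "patientId")])$patientId)
  expect_true(any(perPatient >= 2))
  # counter-based seeding: a video's content is order-independent
  ds2 <- generateDataset(nVideos = 3, framesPerVideo = 2,
                         template = tiny_scene(), seed = 3)
  expect_identical(pixels(ds$frames[[1]]), pixels(ds2$frames[[1]]))
  # minimal case
  one <- generateDataset(nVideos = 1, framesPerVideo = 1,
                         template = tiny_scene(), seed = 5)
  expect_identical(nrow(one$manifest), 1L)
})

test_that("patient-wise splits have zero patient overlap", {
  ds <- generateDataset(nVideos = 11, framesPerVideo = 2,
                        template = tiny_scene(), seed = 9)
  sp <- splitByPatient(ds, "patient5")
  expect_true(checkPatientLeakage(sp$train, sp$test))
  expect_gt(length(sp$test$frames), 0)
  pidTe <- unique(vapply(sp$test$frames, function(f) f@patientId, ""))
  expect_identical(pidTe, "patient5")
})

test_that("invalid scene parameters are rejected", {
  expect_error(SyntheticSceneParams(lumenRadii = c(40, 40)), "radii")
  expect_error(SyntheticSceneParams(nFrames = 0L), "nFrames")
  expect_error(SyntheticSceneParams(
    artifactRates = c(specularity = 2, debris = 0, blur = 0,
                      bleeding_tint = 0, center_frame_corruption = 0)),
    "probabilit")
})
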