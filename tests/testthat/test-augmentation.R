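test_that("sampled augmentation parameters are seeded and in range", {
  expect_identical(sampleAugmentation(7), sampleAugmentation(7))
  pars <- lapply(1:500, sampleAugmentation)
  zooms <- vapply(pars, function(p) p@zoomFactor, 0)
  expect_true(all(zooms >= 0.98 & zooms <= 1.02))
  rots <- vapply(pars, function(p) p@rotationQuarterTurns, 0L)
  expect_true(all(rots %in% 0:3))
})

test_that("rotation draws are uniform over the four quarter turns", {
  # binomial bound at p = 0.25 over 10,000 draws
  rots <- vapply(1:10000, function(s)
    sampleAugmentation(s)@rotationQuarterTurns, 0L)
  freq <- tabulate(rots + 1L, 4L) / length(rots)
  expect_true(all(freq >= 0.22 & freq <= 0.28))
})

test_that("identity parameters reproduce image and mask bitwise", {
  f <- rand_frame(12, 12, seed = 1)
  m <- rand_mask(12, 12, seed = 2)
  id <- AugmentationParams(0L, FALSE, FALSE, 1.0)
  out <- applyAugmentation(f, m, id)
  expect_identical(pixels(out$image), pixels(f))
  expect_identical(pixels(out$mask), pixels(m))
})

test_that("rotations close after four turns and flips are involutions", {
  f <- rand_frame(10, 14, seed = 3)
  m <- rand_mask(10, 14, seed = 4)
  r1 <- AugmentationParams(1L)
  cur <- list(image = f, mask = m)
  for (i in 1:4) cur <- applyAugmentation(cur$image, cur$mask, r1)
  expect_identical(pixels(cur$image), pixels(f))
  expect_identical(pixels(cur$mask), pixels(m))
  for (par in list(AugmentationParams(hflip = TRUE),
                   AugmentationParams(vflip = TRUE))) {
    once <- applyAugmentation(f, m, par)
    twice <- applyAugmentation(once$image, once$mask, par)
    expect_identical(pixels(twice$image), pixels(f))
    expect_identical(pixels(twice$mask), pixels(m))
  }
})

test_that("zoom-free transforms conserve mask foreground and TP counts", {
  predM <- rand_mask(16, 16, seed = 5)
  truthM <- rand_mask(16, 16, seed = 6)
  f <- rand_frame(16, 16, seed = 7)
  for (s in 1:10) {
    par <- sampleAugmentation(s)
    par@zoomFactor <- 1.0  # exact pixel bijection
    ap <- applyAugmentation(f, predM, par)$mask
    at <- applyAugmentation(f, truthM, par)$mask
    expect_identical(sum(pixels(ap)), sum(pixels(predM)))
    cc0 <- confusionCounts(predM, truthM)
    cc1 <- confusionCounts(ap, at)
    expect_identical(cc1@tp, cc0@tp)
    expect_identical(cc1@fp, cc0@fp)
  }
})

test_that("masks stay binary and shapes are preserved under zoom", {
  f <- rand_frame(16, 16, seed = 8)
  m <- rand_mask(16, 16, seed = 9)
  for (z in c(0.98, 0.995, 1.01, 1.02)) {
    par <- AugmentationParams(zoomFactor = z)
    out <- applyAugmentation(f, m, par)
    expect_identical(dim(pixels(out$image)), dim(pixels(f)))
    expect_identical(dim(pixels(out$mask)), dim(pixels(m)))
    expect_true(all(pixels(out$mask) %in% c(0, 1)))
  }
})

test_that("triplets receive one coherent transform and provenance survives", {
  fr <- lapply(0:2, function(t) rand_frame(12, 12, seed = 20 + t, t = t,
                                           patientId = "patientX"))
  tri <- makeTriplets(fr, "drop_edges")[[1]]
  m <- rand_mask(12, 12, seed = 23)
  par <- AugmentationParams(1L, hflip = TRUE)
  out <- applyAugmentation(tri, m, par)
  for (k in 1:3) {
    solo <- applyAugmentation(fr[[k]], m, par)
    expect_identical(pixels(out$image@frames[[k]]), pixels(solo$image))
  }
  expect_identical(out$image@frames[[2]]@patientId, "patientX")
  expect_error(applyAugmentation(rand_frame(12, 12), rand_mask(8, 8), par),
               "alignment")
})

test_that("offline dataset augmentation keeps patient provenance", {
  ds <- generateDataset(nVideos = 2, framesPerVideo = 2,
                        template = tiny_scene(), seed = 31)
  aug <- augmentDataset(ds, copiesPerFrame = 2, seed = 5)
  expect_length(aug$frames, 3 * length(ds$frames))
  pid <- vapply(aug$frames, function(f) f@patientId, "")
  expect_identical(sort(unique(pid)),
                   sort(unique(vapply(ds$frames,
                                      function(f) f@patientId, ""))))
})
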