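test_that("residual U-Net construction honors its spec contract", {
  m <- tiny_resunet(16, seed = 1)
  f <- rand_frame(16, 16, seed = 1)
  mp <- predictSingle(m, f)
  expect_s4_class(mp, "ProbabilityMap")
  expect_identical(dim(pixels(mp)), c(16L, 16L))
  # sigmoid output: valid probabilities (an untrained net can saturate to
  # the representable endpoints)
  expect_true(all(pixels(mp) >= 0 & pixels(mp) <= 1))
  f0 <- Frame(array(0, c(16, 16, 3)))
  p0 <- pixels(predictSingle(m, f0))
  expect_true(all(p0 >= 0 & p0 <= 1))
  # indivisible input dims are a spec error
  expect_error(ResUNetSpec(depth = 4L, baseFilters = 8L,
                           inputShape = c(50L, 50L, 3L)), "divisible")
})

test_that("architecture size is a pure function of the spec", {
  a <- tiny_resunet(16, seed = 1)
  b <- tiny_resunet(16, seed = 999)
  expect_identical(parameterCount(a), parameterCount(b))
  expect_false(identical(a@params$head$W, b@params$head$W))
})

test_that("inference is deterministic and order-preserving", {
  m <- tiny_resunet(16, seed = 2)
  f <- rand_frame(16, 16, seed = 5)
  expect_identical(pixels(predictSingle(m, f)),
                   pixels(predictSingle(m, f)))
  frames <- lapply(1:3, function(s) rand_frame(16, 16, seed = s,
                                               t = s - 1L))
  maps <- LumenSeg:::predict_frames_batch(m, frames)
  for (i in 1:3)
    expect_equal(pixels(maps[[i]]), pixels(predictSingle(m, frames[[i]])),
                 tolerance = 1e-12)
  # a core built for nK channels refuses RGB frames
  mk <- tiny_resunet(16, seed = 3, channels = 8L)
  expect_error(predictSingle(mk, f), "channels")
})

test_that("frames at a different native size are resized for inference", {
  m <- tiny_resunet(16, seed = 4)
  f <- rand_frame(24, 20, seed = 6)
  mp <- predictSingle(m, f)
  expect_identical(dim(pixels(mp)), c(24L, 20L))
})

test_that("instance adapter reduces detections per its contract", {
  empty <- instancesToLumenMap(list(), numeric(0))
  expect_true(all(pixels(empty) == 0))
  # single surviving instance passes through unchanged under "best"
  soft <- matrix(0, 16, 16); soft[4:8, 4:8] <- 0.9
  one <- instancesToLumenMap(list(soft), 0.9, confidenceThreshold = 0.7)
  expect_identical(pixels(one), soft)
  # below-threshold instances are discarded
  low <- instancesToLumenMap(list(soft), 0.5, confidenceThreshold = 0.7)
  expect_true(all(pixels(low) == 0))
  expect_error(instancesToLumenMap(list(soft), c(0.5, 0.9)), "length")
})

test_that("union merge equals the brute-force pixelwise maximum", {
  withr::with_seed(42, {
    masks <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
  })
  got <- pixels(instancesToLumenMap(masks, c(0.8, 0.9, 0.95),
                                    confidenceThreshold = 0.7,
                                    mergePolicy = "union"))
  want <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    want[i, j] <- max(masks[[1]][i, j], masks[[2]][i, j], masks[[3]][i, j])
  expect_identical(got, want)
  # monotonicity: adding an instance never decreases any pixel
  got2 <- pixels(instancesToLumenMap(c(masks, list(matrix(0.99, 8, 8))),
                                     c(0.8, 0.9, 0.95, 0.8),
                                     confidenceThreshold = 0.7,
                                     mergePolicy = "union"))
  expect_true(all(got2 >= got))
})

test_that("the instance core localizes the dark lumen on a clean frame", {
  v <- generateVideo(SyntheticSceneParams(
    nFrames = 1L, artifactRates = c(specularity = 0, debris = 0, blur = 0,
                                    bleeding_tint = 0,
                                    center_frame_corruption = 0),
    noiseSigma = 0, seed = 5))
  m2 <- buildInstanceSegmenter()
  mp <- predictSingle(m2, v$frames[[1]])
  inside <- pixels(mp)[pixels(v$masks[[1]]) == 1]
  outside <- pixels(mp)[pixels(v$masks[[1]]) == 0]
  expect_gt(mean(inside), mean(outside))
  expect_gt(dsc(confusionCounts(binarize(mp, 0.5), v$masks[[1]])), 0.3)
})

test_that("instance spec validity enforces the configuration surface", {
  expect_error(InstanceSegSpec(minDetectionConfidence = 0.95), "0.5")
  expect_error(InstanceSegSpec(anchorScales = c(64L, 32L)), "increasing")
  expect_error(InstanceSegSpec(backbone = "vgg"), "backbone")
})
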