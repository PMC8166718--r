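make_triplet <- function(p, q, seed = 1, fill = NULL) {
  fr <- lapply(0:2, function(t) {
    px <- if (is.null(fill))
      withr::with_seed(seed + t, array(runif(p * q * 3), c(p, q, 3)))
    else array(fill, c(p, q, 3))
    Frame(px, t = t)
  })
  makeTriplets(fr, "drop_edges")[[1]]
}

test_that("the 3D front's shape chain holds over random sizes", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      p <- sample(8:24, 1); q <- sample(8:24, 1); nk <- sample(1:6, 1)
      sp <- TemporalExtensionSpec(nK = nk)
      h <- temporalFront(make_triplet(p, q, seed = rep), sp,
                         frontWeights(sp, seed = rep))
      expect_identical(attr(h, "rawDim"),
                       c(1L, p - 2L, q - 2L, as.integer(nk)))
      expect_identical(dim(h), c(p, q, as.integer(nk)))
      # the padded ring is exactly zero
      expect_true(all(h[1, , ] == 0, h[p, , ] == 0,
                      h[, 1, ] == 0, h[, q, ] == 0))
    }
  })
})

test_that("linearity and bias broadcast degenerate cases", {
  sp <- TemporalExtensionSpec(nK = 2L, activation = "linear")
  w <- frontWeights(sp, seed = 1)
  # all-zero triplet with zero bias -> all-zero features
  h <- temporalFront(make_triplet(10, 10, fill = 0), sp, w)
  expect_true(all(h == 0))
  # all-zero weights -> the bias broadcast over the interior
  w0 <- list(W = w$W * 0, b = c(0.3, -0.2))
  h0 <- temporalFront(make_triplet(10, 10, seed = 5), sp, w0)
  expect_true(all(h0[2:9, 2:9, 1] == 0.3))
  expect_true(all(h0[2:9, 2:9, 2] == -0.2))
})

test_that("spec invariants are enforced", {
  expect_error(TemporalExtensionSpec(nK = 3L, kernelSpatial = c(1L, 1L)),
               "fixed")
  expect_error(TemporalExtensionSpec(nK = 0L), "nK")
  expect_error(TemporalExtensionSpec(nK = 3L, r = 5L), "fixed")
  expect_error(TemporalExtensionSpec(nK = 3L, activation = "tanh"),
               "activation")
})

test_that("extension matches cores and counts parameters exactly", {
  core3 <- tiny_resunet(16, seed = 1)
  M <- extendModel(core3, TemporalExtensionSpec(nK = 3L), seed = 2)
  # added parameters: nK*(r*3*3*n_c) + nK = 3*81 + 3 = 246
  expect_identical(parameterCount(M) - parameterCount(core3), 246L)
  # nK must match the core's input channels
  expect_error(extendModel(core3, TemporalExtensionSpec(nK = 8L)),
               "configuration error")
  # the fixed-input instance core only accepts nK = 3
  m2 <- buildInstanceSegmenter()
  expect_error(extendModel(m2, TemporalExtensionSpec(nK = 5L)),
               "configuration error")
  M2 <- extendModel(m2, TemporalExtensionSpec(nK = 3L))
  expect_s4_class(M2, "ExtendedModel")
})

test_that("triplet prediction is deterministic and indexed by the center", {
  core <- tiny_resunet(16, seed = 3)
  M <- extendModel(core, TemporalExtensionSpec(nK = 3L), seed = 4)
  tri <- make_triplet(16, 16, seed = 9)
  a <- predictTriplet(M, tri)
  b <- predictTriplet(M, tri)
  expect_identical(pixels(a), pixels(b))
  expect_identical(frameIndex(a), tri@centerIndex)
  expect_identical(dim(pixels(a)), c(16L, 16L))
  expect_true(all(pixels(a) >= 0 & pixels(a) <= 1))
  # static scene: extended and core predictions share the shape contract
  f <- rand_frame(16, 16, seed = 10)
  triS <- makeTriplets(list(f), "replicate_edge")[[1]]
  expect_identical(dim(pixels(predictTriplet(M, triS))),
                   dim(pixels(predictSingle(core, f))))
})

test_that("the temporal-mean front initialization averages across time", {
  sp <- TemporalExtensionSpec(nK = 3L, activation = "linear")
  w <- frontWeights(sp, init = "temporal_mean")
  fr <- lapply(0:2, function(t)
    Frame(array(0.3 * (t + 1), c(8, 8, 3)), t = t))
  tri <- makeTriplets(fr, "drop_edges")[[1]]
  h <- temporalFront(tri, sp, w)
  # interior pixels hold the across-time mean 0.3*(1+2+3)/3 = 0.6
  # (single-precision convolution arithmetic)
  expect_equal(h[4, 4, 1], 0.6, tolerance = 1e-6)
  expect_error(frontWeights(TemporalExtensionSpec(nK = 4L),
                            init = "temporal_mean"), "nK = 3")
})
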