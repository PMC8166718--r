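test_that("the ensemble mean matches a brute-force per-pixel oracle", {
  for (rep in 1:5) {
    maps <- lapply(1:4, function(i) rand_map(16, 16, seed = rep * 10 + i))
    fused <- ensemblePredict(maps)
    oracle <- bf_mean(lapply(maps, pixels))
    expect_equal(pixels(fused), oracle, tolerance = 1e-15)
  }
})

test_that("averaging is idempotent, permutation-invariant and bounded", {
  m <- rand_map(12, 12, seed = 1)
  same <- ensemblePredict(list(m, m, m, m))
  expect_identical(pixels(same), pixels(m))
  maps <- lapply(1:4, function(i) rand_map(12, 12, seed = i))
  a <- ensemblePredict(maps)
  b <- ensemblePredict(rev(maps))
  expect_equal(pixels(a), pixels(b), tolerance = 1e-15)
  lo <- Reduce(pmin, lapply(maps, pixels))
  hi <- Reduce(pmax, lapply(maps, pixels))
  expect_true(all(pixels(a) >= lo - 1e-15 & pixels(a) <= hi + 1e-15))
  # worked value: (1, 0, 0, 0) -> 0.25
  ones <- ProbabilityMap(matrix(1, 4, 4))
  zero <- ProbabilityMap(matrix(0, 4, 4))
  expect_true(all(pixels(ensemblePredict(list(ones, zero, zero,
                                              zero))) == 0.25))
})

test_that("misaligned or missing members are rejected", {
  expect_error(ensemblePredict(list()), "input error")
  a <- rand_map(8, 8, seed = 1)
  b <- rand_map(10, 10, seed = 2)
  expect_error(ensemblePredict(list(a, b)), "alignment")
  c2 <- ProbabilityMap(pixels(a), t = 5L)
  expect_error(ensemblePredict(list(a, c2)), "alignment")
})

test_that("binarization follows the >= convention and validates input", {
  low <- ProbabilityMap(matrix(0.25, 8, 8))
  expect_true(all(pixels(binarize(low, 0.5)) == 0))
  at <- ProbabilityMap(matrix(0.5, 8, 8))
  expect_true(all(pixels(binarize(at, 0.5)) == 1))
  bin <- ProbabilityMap(rand_mask(8, 8, seed = 3)@pixels)
  expect_identical(pixels(binarize(bin, 0.5)), pixels(bin))
  expect_error(binarize(low, 0), "config error")
  expect_error(binarize(low, 1), "config error")
})

test_that("ensemble configs cover the ablation subsets and validate", {
  for (mem in list(c("m1", "m2"), c("M1", "M2"), c("M1", "m1"),
                   c("M2", "m2"), c("m1", "m2", "M1", "M2")))
    expect_s4_class(EnsembleConfig(mem), "EnsembleConfig")
  expect_error(EnsembleConfig(c("m1", "m1")), "unique")
  expect_error(EnsembleConfig(character(0)), "members")
  expect_error(EnsembleConfig("m1", binarizeThreshold = 1), "0, 1|\\(0, 1\\)")
  expect_identical(members(EnsembleConfig(c("m1", "M1"))), c("m1", "M1"))
})

test_that("ensembleSegment fuses member maps through one code path", {
  core <- tiny_resunet(16, seed = 1)
  M1 <- extendModel(tiny_resunet(16, seed = 2, tag = "M1core"),
                    TemporalExtensionSpec(nK = 3L), seed = 3)
  m2 <- buildInstanceSegmenter()
  M2 <- extendModel(buildInstanceSegmenter(tag = "M2core"),
                    TemporalExtensionSpec(nK = 3L), tag = "M2")
  models <- list(m1 = core, m2 = m2, M1 = M1, M2 = M2)
  fr <- lapply(0:2, function(t) rand_frame(16, 16, seed = 30 + t, t = t))
  tri <- makeTriplets(fr, "drop_edges")[[1]]
  out <- ensembleSegment(models, EnsembleConfig(), tri)
  expect_s4_class(out$map, "ProbabilityMap")
  expect_s4_class(out$mask, "BinaryMask")
  expect_length(out$memberMaps, 4L)
  manual <- ensemblePredict(out$memberMaps)
  expect_identical(pixels(out$map), pixels(manual))
  expect_error(ensembleSegment(models[c("m1", "m2")], EnsembleConfig(), tri),
               "dependency error")
})
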