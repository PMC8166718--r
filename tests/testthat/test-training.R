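# Tiny desk-scale settings: 16x16 frames, depth-2 base-8 networks, a few
# epochs -- enough to exercise every contract without real training cost.

tiny_ds <- function(nVideos = 2, framesPerVideo = 3, seed = 41, ...) {
  generateDataset(nVideos = nVideos, framesPerVideo = framesPerVideo,
                  template = tiny_scene(...), seed = seed)
}

test_that("patient folds are exclusive, exhaustive and seeded", {
  pats <- paste0("patient", 1:5)
  f <- makePatientFolds(pats, 5, seed = 1)
  expect_length(f@folds, 5L)
  vals <- unlist(lapply(f@folds, `[[`, "val"))
  expect_setequal(vals, pats)        # each patient validates exactly once
  expect_length(vals, 5L)
  for (fd in f@folds) {
    expect_length(fd$val, 1L)        # five patients, five folds: LOPO
    expect_length(intersect(fd$train, fd$val), 0L)
  }
  expect_identical(makePatientFolds(pats, 5, seed = 9),
                   makePatientFolds(pats, 5, seed = 9))
  expect_error(makePatientFolds(pats, 6), "config error")
})

test_that("fold boundaries are leak-free even with augmented copies", {
  ds <- tiny_ds(nVideos = 4, seed = 43)
  aug <- augmentDataset(ds, copiesPerFrame = 1, seed = 2)
  pid <- vapply(aug$frames, function(f) f@patientId, "")
  folds <- makePatientFolds(unique(pid), 2, seed = 3)
  for (fd in folds@folds) {
    tr <- LumenSeg:::subset_data(aug, pid %in% fd$train)
    va <- LumenSeg:::subset_data(aug, pid %in% fd$val)
    expect_true(checkPatientLeakage(tr, va))
  }
})

test_that("zero learning rate leaves weights untouched", {
  ds <- tiny_ds()
  m <- tiny_resunet(16, seed = 5)
  fit <- trainModel(m, ds, ds, lr = 0, bs = 4L, epochs = 1L, seed = 1)
  expect_identical(fit$model@params$head$W, m@params$head$W)
  expect_identical(fit$model@params$enc[[1]]$conv1$W,
                   m@params$enc[[1]]$conv1$W)
  expect_identical(nrow(fit$history), 1L)
})

test_that("training is deterministic and reduces the loss", {
  ds <- tiny_ds(seed = 47)
  a <- trainModel(tiny_resunet(16, seed = 6), ds, ds, lr = 1e-3, bs = 4L,
                  epochs = 2L, seed = 11)
  b <- trainModel(tiny_resunet(16, seed = 6), ds, ds, lr = 1e-3, bs = 4L,
                  epochs = 2L, seed = 11)
  expect_identical(a$history, b$history)
  expect_identical(a$model@params$head$W, b$model@params$head$W)
  expect_lt(a$history$trainLoss[2], a$history$trainLoss[1])
  expect_true(a$model@trained)
  expect_error(trainModel(tiny_resunet(16), list(frames = list(),
                                                 masks = list()), ds),
               "input error")
})

test_that("the returned checkpoint is the best-validation-DSC epoch", {
  ds <- tiny_ds(seed = 53)
  fit <- trainModel(tiny_resunet(16, seed = 7), ds, ds, lr = 1e-3, bs = 4L,
                    epochs = 3L, seed = 13)
  best <- max(fit$history$valDsc)
  # re-scoring the returned model reproduces the best epoch's val DSC
  maps <- LumenSeg:::predict_frames_batch(fit$model, ds$frames)
  again <- LumenSeg:::mean_dsc_maps(maps, ds$masks)
  expect_equal(again, best, tolerance = 1e-12)
})

test_that("the instance core sweep selects and freezes its tunables", {
  ds <- tiny_ds(seed = 59, illuminationFalloff = 0.6)
  m2 <- buildInstanceSegmenter()
  fit <- trainModel(m2, ds, ds, seed = 1)
  expect_true(fit$model@trained)
  expect_true(fit$model@spec@minDetectionConfidence %in% seq(0.5, 0.9, 0.1))
  expect_identical(nrow(fit$history), 15L)  # 3 sigmas x 5 confidences
})

test_that("grid search enumerates combos x folds and applies the tie rule", {
  ds <- tiny_ds(nVideos = 4, seed = 61)
  # fixed init so combos differing only in a vanishing lr genuinely tie
  build <- function(lr, bs, nK, seed) tiny_resunet(16, seed = 1)
  folds <- makePatientFolds(unique(LumenSeg:::frame_pids(ds)), 2, seed = 1)
  # singleton space
  gs1 <- gridSearch(list(learning_rates = 1e-3, batch_sizes = 4L),
                    folds, ds, build, epochs = 1L, seed = 1)
  expect_identical(nrow(gs1$cvTable), 2L)   # 1 combo x 2 folds
  expect_identical(gs1$best$lr, 1e-3)
  # two vanishingly small learning rates tie; the smaller one wins
  gs2 <- gridSearch(list(learning_rates = c(1e-12, 1e-11),
                         batch_sizes = 4L),
                    folds, ds, build, epochs = 1L, seed = 1)
  expect_identical(nrow(gs2$cvTable), 4L)
  expect_identical(gs2$best$lr, 1e-12)
  # selection is re-derivable from the emitted table
  agg <- aggregate(valDsc ~ lr, data = gs2$cvTable, FUN = mean)
  expect_identical(min(agg$lr[agg$valDsc == max(agg$valDsc)]), gs2$best$lr)
})

test_that("the printed grid has the documented dimensions", {
  space <- list(learning_rates = c(1e-3, 1e-4, 1e-5, 1e-6),
                batch_sizes = c(4L, 8L, 16L))
  combos <- expand.grid(lr = space$learning_rates,
                        bs = space$batch_sizes)
  expect_identical(nrow(combos), 12L)  # x 5 folds = 60 training runs
})

test_that("train/validation splitting honors the ratio and its guards", {
  ds <- tiny_ds(nVideos = 2, framesPerVideo = 5, seed = 67)  # 10 frames
  sp <- splitTrainVal(ds, 0.6, seed = 1)
  expect_length(sp$train$frames, 6L)
  expect_length(sp$val$frames, 4L)
  expect_error(splitTrainVal(ds, 1.0), "config error")
  expect_error(splitTrainVal(ds, 0), "config error")
  spp <- splitTrainVal(ds, 0.5, seed = 1, patientWise = TRUE)
  expect_true(checkPatientLeakage(spp$train, spp$val))
})

test_that("finalFit demands hyperparameters and returns one model per member", {
  ds <- tiny_ds(seed = 71)
  models <- list(m1 = tiny_resunet(16, seed = 1),
                 m2 = buildInstanceSegmenter())
  expect_error(finalFit(models, list(m2 = NULL), ds), "order-of-operations")
  out <- finalFit(models, list(m1 = list(lr = 1e-3, bs = 4L)), ds,
                  epochs = 1L, seed = 1)
  expect_setequal(names(out), c("m1", "m2"))
  expect_true(all(vapply(out, function(x) !is.null(x$model), TRUE)))
})

test_that("the ablation suite covers 9 configurations through one path", {
  ds <- tiny_ds(seed = 73)
  models <- list(
    m1 = tiny_resunet(16, seed = 1),
    m2 = buildInstanceSegmenter(),
    M1 = extendModel(tiny_resunet(16, seed = 2, tag = "M1core"),
                     TemporalExtensionSpec(nK = 3L), seed = 3),
    M2 = extendModel(buildInstanceSegmenter(tag = "M2core"),
                     TemporalExtensionSpec(nK = 3L)))
  ab <- runAblation(models, ds)
  expect_identical(length(unique(ab$perFrame$model)), 9L)
  expect_identical(nrow(ab$perFrame), 9L * length(ds$frames))
  expect_s3_class(ab$summary, "data.frame")
  expect_identical(nrow(ab$comparison$pairwise), 6L)  # 4 singles pairwise
  expect_error(runAblation(models[c("m1", "m2")], ds), "dependency error")
  expect_error(runAblation(models, ds, configs = list(c("m1", "m1"))),
               "config error")
})
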