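test_that("confusion counts equal the per-pixel loop oracle", {
  for (rep in 1:20) {
    p <- rand_mask(16, 16, seed = rep)@pixels
    g <- rand_mask(16, 16, seed = 100 + rep)@pixels
    cc <- confusionCounts(p, g)
    o <- bf_confusion(p, g)
    expect_identical(c(cc@tp, cc@fp, cc@fn, cc@tn), as.numeric(o))
    expect_identical(cc@tp + cc@fp + cc@fn + cc@tn, 256)
  }
  expect_error(confusionCounts(matrix(0, 4, 4), matrix(0, 5, 5)),
               "alignment")
})

test_that("perfect and empty predictions hit the exact corner values", {
  g <- matrix(0, 8, 8); g[1:5, 1:2] <- 1
  cc <- confusionCounts(g, g)
  expect_identical(c(cc@tp, cc@fp, cc@fn, cc@tn), c(10, 0, 0, 54))
  expect_identical(diceLoss(cc), 0)
  e <- confusionCounts(matrix(0, 8, 8), g)
  expect_identical(c(e@tp, e@fn), c(0, 10))
  expect_identical(diceLoss(e), 1)
  r <- evaluateFrame(matrix(0, 8, 8), g)
  expect_identical(c(r$dsc, r$precision, r$recall), c(0, 0, 0))
})

test_that("the DSC identity and the worked 0.75 case hold", {
  # DSC + L_DSC = 1 on random counts
  withr::with_seed(7, {
    for (i in 1:200) {
      cc <- ConfusionCounts(tp = rpois(1, 20), fp = rpois(1, 10),
                            fn = rpois(1, 10), tn = rpois(1, 100))
      expect_equal(dsc(cc) + diceLoss(cc), 1, tolerance = 1e-15)
    }
  })
  cc <- ConfusionCounts(tp = 6, fp = 2, fn = 2, tn = 54)
  expect_equal(diceLoss(cc), 0.25, tolerance = 1e-15)
  g <- matrix(0, 4, 4); g[1:2, 1:4] <- 1
  p <- matrix(0, 4, 4); p[1:2, 1:3] <- 1; p[3, 1:2] <- 1
  r <- evaluateFrame(p, g)
  expect_equal(c(r$dsc, r$precision, r$recall), c(0.75, 0.75, 0.75),
               tolerance = 1e-15)
})

test_that("degenerate denominators follow the documented conventions", {
  # both masks empty: agreement on absence scores 1 everywhere
  r <- evaluateFrame(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_identical(c(r$dsc, r$precision, r$recall), c(1, 1, 1))
  expect_identical(diceLoss(ConfusionCounts(0, 0, 0, 16)), 0)
  # empty prediction, non-empty truth
  g <- matrix(0, 4, 4); g[1, 1] <- 1
  r2 <- evaluateFrame(matrix(0, 4, 4), g)
  expect_identical(c(r2$dsc, r2$precision, r2$recall), c(0, 0, 0))
  expect_error(ConfusionCounts(-1, 0, 0, 1), "non-negative")
})

test_that("metrics are invariant to joint transposition", {
  p <- rand_mask(12, 9, seed = 1)@pixels
  g <- rand_mask(12, 9, seed = 2)@pixels
  expect_identical(evaluateFrame(p, g)[, 3:5],
                   evaluateFrame(t(p), t(g))[, 3:5])
})

test_that("soft Dice agrees with hard Dice on binary maps", {
  p <- rand_mask(16, 16, seed = 3)@pixels
  g <- rand_mask(16, 16, seed = 4)@pixels
  expect_equal(softDiceLoss(p, g), diceLoss(confusionCounts(p, g)),
               tolerance = 1e-4)
})

test_that("Kruskal-Wallis comparisons match the rank-based closed form", {
  # identical samples: H ~ 0, p ~ 1
  same <- compareModels(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_lt(same$H, 1e-8)
  expect_gt(same$p, 0.99)
  # hand-ranked oracle for {1,2,3} vs {101,102,103}: ranks 1..6,
  # H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  r <- compareModels(list(a = c(1, 2, 3), b = c(101, 102, 103)))
  H <- 12 / 42 * (36 / 3 + 225 / 3) - 21
  expect_equal(r$H, H, tolerance = 1e-12)
  expect_equal(r$p, pchisq(H, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_identical(r$pairwise$stars[1], "*")  # p = 0.0495
  # strongly separated large samples earn stars
  big <- compareModels(list(a = rep(c(0.1, 0.12, 0.11), 10),
                            b = rep(c(0.9, 0.92, 0.91), 10)))
  expect_identical(big$pairwise$stars[1], "***")
  expect_error(compareModels(list(a = 1:3)), "input error")
  expect_error(compareModels(list(a = 1:3, b = 2)), "input error")
})

test_that("aggregation reports frame means and quartiles per model", {
  df <- rbind(evaluateFrames(list(rand_mask(8, 8, 1), rand_mask(8, 8, 2)),
                             list(rand_mask(8, 8, 1), rand_mask(8, 8, 3)),
                             "mA"),
              evaluateFrames(list(rand_mask(8, 8, 4)),
                             list(rand_mask(8, 8, 4)), "mB"))
  agg <- aggregateMetrics(df)
  expect_setequal(agg$model, c("mA", "mB"))
  expect_identical(agg$dsc[agg$model == "mB"], 1)
  expect_true(all(c("dsc_q1", "dsc_median", "dsc_q3") %in% names(agg)))
})

test_that("confusion overlays color the four classes correctly", {
  p <- matrix(0, 4, 4); p[1, 1] <- 1; p[2, 2] <- 1
  g <- matrix(0, 4, 4); g[1, 1] <- 1; g[3, 3] <- 1
  ov <- overlayConfusion(p, g)
  expect_identical(ov[1, 1, ], c(1, 1, 0))   # TP yellow
  expect_identical(ov[2, 2, ], c(1, 0.6, 0.8))  # FP pink
  expect_identical(ov[3, 3, ], c(0, 0, 1))   # FN blue
  expect_identical(ov[4, 4, ], c(0, 0, 0))   # TN black
})
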