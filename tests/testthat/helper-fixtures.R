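# Shared fixtures and brute-force oracles for the test suite. Everything is
# generated in code; no binary fixtures on disk.

rand_frame <- function(p = 16, q = 16, seed = 1, t = 0L, videoId = "v1",
                       patientId = "p1") {
  px <- withr::with_seed(seed, array(runif(p * q * 3), c(p, q, 3)))
  Frame(px, t = t, videoId = videoId, patientId = patientId)
}

rand_mask <- function(p = 16, q = 16, seed = 1, frac = 0.3, t = 0L,
                      videoId = "v1") {
  m <- withr::with_seed(seed, matrix(as.numeric(runif(p * q) < frac), p, q))
  BinaryMask(m, t = t, videoId = videoId)
}

rand_map <- function(p = 16, q = 16, seed = 1, t = 0L) {
  ProbabilityMap(withr::with_seed(seed, matrix(runif(p * q), p, q)), t = t)
}

# 16x16 fixture template used where a full video is overkill
tiny_scene <- function(nFrames = 3L, ...) {
  SyntheticSceneParams(frameSize = c(16L, 16L), lumenRadii = c(4, 3),
                       lumenCenterAmplitude = 2, nFrames = nFrames, ...)
}

tiny_resunet <- function(p = 16, seed = 1, channels = 3L, tag = "m1") {
  buildResUNet(ResUNetSpec(depth = 2L, baseFilters = 8L,
                           inputShape = c(p, p, channels)),
               seed = seed, tag = tag)
}

# Brute-force per-pixel confusion tally (the oracle the vectorized counts
# are checked against)
bf_confusion <- function(pred, truth) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
      else if (pred[i, j] == 1) fp <- fp + 1L
      else if (truth[i, j] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force per-pixel mean of a list of matrices
bf_mean <- function(mats) {
  out <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  for (i in seq_len(nrow(out)))
    for (j in seq_len(ncol(out))) {
      s <- 0
      for (m in mats) s <- s + m[i, j]
      out[i, j] <- s / length(mats)
    }
  out
}
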