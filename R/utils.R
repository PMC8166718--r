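# Small internal helpers: seeded RNG scoping, deterministic sub-seed
# derivation, and resize wrappers around EBImage.

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based sub-seed: independent streams from one master seed, always
# below 2^31 so set.seed() accepts it.
derive_seed <- function(master, stream) {
  as.integer((as.numeric(master) %% 1000003 + 1) * 1009 +
               as.numeric(stream) * 7919) %% 2147483629L
}

# Bilinear resize of a p x q (x c) numeric array; returns same rank.
resize_bilinear <- function(x, p, q) {
  img <- EBImage::Image(x,
    colormode = if (length(dim(x)) == 3L) "Color" else "Grayscale")
  out <- EBImage::resize(img, w = p, h = q, filter = "bilinear")
  arr <- EBImage::imageData(out)
  pmin(pmax(arr, 0), 1)
}

# Nearest-neighbour resize for masks (keeps binarity).
resize_nearest <- function(x, p, q) {
  img <- EBImage::Image(x, colormode = "Grayscale")
  out <- EBImage::resize(img, w = p, h = q, filter = "none")
  EBImage::imageData(out)
}

# Stack a list of Frames into an (h, w, 3, n) batch array.
stack_frames <- function(frames) {
  d <- dim(frames[[1L]]@pixels)
  arr <- array(0, c(d[1L], d[2L], 3L, length(frames)))
  for (i in seq_along(frames)) arr[, , , i] <- frames[[i]]@pixels
  arr
}

# Stack a list of BinaryMasks into an (h, w, n) array.
stack_masks <- function(masks) {
  d <- dim(masks[[1L]]@pixels)
  arr <- array(0, c(d[1L], d[2L], length(masks)))
  for (i in seq_along(masks)) arr[, , i] <- masks[[i]]@pixels
  arr
}

# Stack a FrameTriplet into (h, w, 9, 1): frame-major channel order
# (I(t-1) RGB, I(t) RGB, I(t+1) RGB).
stack_triplet <- function(triplet) {
  d <- dim(triplet@frames[[1L]]@pixels)
  arr <- array(0, c(d[1L], d[2L], 9L, 1L))
  for (f in 1:3)
    arr[, , (3L * (f - 1L) + 1L):(3L * f), 1L] <- triplet@frames[[f]]@pixels
  arr
}

# Stack many triplets into (h, w, 9, n).
stack_triplets <- function(triplets) {
  d <- dim(triplets[[1L]]@frames[[1L]]@pixels)
  arr <- array(0, c(d[1L], d[2L], 9L, length(triplets)))
  for (i in seq_along(triplets))
    for (f in 1:3)
      arr[, , (3L * (f - 1L) + 1L):(3L * f), i] <-
        triplets[[i]]@frames[[f]]@pixels
  arr
}
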