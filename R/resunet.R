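#' Build the residual U-Net core model (m1)
#'
#' Constructs an encoder--decoder segmentation network whose blocks are
#' residual units: two 3x3 convolutions (with optional batch normalization)
#' plus an identity shortcut, using a 1x1 projection when the channel counts
#' differ. Filters double at each encoder level; upsampling uses 2x2
#' transposed convolutions; skip connections concatenate encoder features
#' into the decoder; a final 1x1 convolution with a sigmoid yields one
#' probability channel. The architecture is a pure function of the spec;
#' weights are He-initialized from \code{seed}.
#'
#' @param spec a \linkS4class{ResUNetSpec}.
#' @param seed integer seed for weight initialization.
#' @param tag model tag stamped on emitted probability maps.
#' @return A \linkS4class{ResUNetModel}.
#' @examples
#' m <- buildResUNet(ResUNetSpec(depth = 3, baseFilters = 16,
#'                               inputShape = c(64, 64, 3)))
#' parameterCount(m)
#' @export
buildResUNet <- function(spec, seed = 1L, tag = "m1") {
  stopifnot(is(spec, "ResUNetSpec"))
  validObject(spec)
  f <- spec@baseFilters
  d <- spec@depth
  cin <- spec@inputShape[3L]
  bn <- spec@useBatchNorm
  params <- with_seed(seed, {
    enc <- vector("list", d)
    ch <- cin
    for (i in seq_len(d)) {
      enc[[i]] <- rb_init(ch, f * 2L^(i - 1L), bn)
      ch <- f * 2L^(i - 1L)
    }
    bottleneck <- rb_init(f * 2L^(d - 1L), f * 2L^d, bn)
    dec <- vector("list", d)
    for (i in seq_len(d)) {
      co <- f * 2L^(i - 1L)
      dec[[i]] <- list(up = list(W = he_up(f * 2L^i, co), b = numeric(co)),
                       block = rb_init(2L * co, co, bn))
    }
    # negative head bias starts predictions near the low foreground prior
    # of endoscopic lumen masks, which stabilizes early Dice-loss training
    head <- list(W = he_w1(f, 1L), b = -2)
    list(enc = enc, bottleneck = bottleneck, dec = dec, head = head)
  })
  new("ResUNetModel", spec = spec, params = params, trained = FALSE,
      tag = tag)
}

# Full forward pass on a batch (h, w, c, n). Returns probabilities
# (h, w, n), a cache for backward, and params with refreshed BN running
# statistics when training.
resunet_fwd <- function(params, spec, x, training = FALSE) {
  d <- spec@depth
  bn <- spec@useBatchNorm
  cache <- list(enc = vector("list", d), pool = vector("list", d),
                dec = vector("list", d))
  for (i in seq_len(d)) {
    r <- rb_fwd(x, params$enc[[i]], bn, training)
    params$enc[[i]] <- r$p
    cache$enc[[i]] <- r$cache
    cache$skip <- c(cache$skip, list(r$y))
    pl <- pool_fwd(r$y)
    cache$pool[[i]] <- list(arg = pl$arg, dimx = dim(r$y))
    x <- pl$y
  }
  r <- rb_fwd(x, params$bottleneck, bn, training)
  params$bottleneck <- r$p
  cache$bt <- r$cache
  x <- r$y
  for (i in rev(seq_len(d))) {
    upIn <- x
    u <- up_fwd(x, params$dec[[i]]$up$W, params$dec[[i]]$up$b)
    sk <- cache$skip[[i]]
    co <- dim(u)[3L]
    dd <- dim(u)
    catx <- array(0, c(dd[1L], dd[2L], 2L * co, dd[4L]))
    catx[, , seq_len(co), ] <- u
    catx[, , co + seq_len(co), ] <- sk
    r <- rb_fwd(catx, params$dec[[i]]$block, bn, training)
    params$dec[[i]]$block <- r$p
    cache$dec[[i]] <- list(upIn = upIn, blockCache = r$cache, co = co)
    x <- r$y
  }
  hd <- conv1_fwd(x, params$head$W, params$head$b)
  cache$head <- x
  z <- hd$y
  p <- sigmoid(z)
  cache$p <- p
  list(p = array(p, dim(p)[c(1L, 2L, 4L)]), cache = cache, params = params)
}

# Backward pass from dL/dp (h, w, n); returns gradients mirroring the
# trainable parameter structure.
resunet_bwd <- function(params, spec, cache, dp) {
  d <- spec@depth
  bn <- spec@useBatchNorm
  pr <- cache$p
  dz <- array(dp, dim(pr)) * pr * (1 - pr)
  g <- list(enc = vector("list", d), dec = vector("list", d))
  hb <- conv1_bwd(list(x = cache$head), params$head$W, dz)
  g$head <- list(W = hb$dW, b = hb$db)
  x <- hb$dx
  dskip <- vector("list", d)
  for (i in seq_len(d)) {
    r <- rb_bwd(params$dec[[i]]$block, bn, cache$dec[[i]]$blockCache, x)
    co <- cache$dec[[i]]$co
    dcat <- r$dx
    dup <- dcat[, , seq_len(co), , drop = FALSE]
    dskip[[i]] <- dcat[, , co + seq_len(co), , drop = FALSE]
    ub <- up_bwd(cache$dec[[i]]$upIn, params$dec[[i]]$up$W, dup)
    g$dec[[i]] <- list(up = list(W = ub$dW, b = ub$db), block = r$g)
    x <- ub$dx
  }
  r <- rb_bwd(params$bottleneck, bn, cache$bt, x)
  g$bottleneck <- r$g
  x <- r$dx
  for (i in rev(seq_len(d))) {
    x <- pool_bwd(x, cache$pool[[i]]$arg, cache$pool[[i]]$dimx)
    x <- x + dskip[[i]]
    r <- rb_bwd(params$enc[[i]], bn, cache$enc[[i]], x)
    g$enc[[i]] <- r$g
    x <- r$dx
  }
  list(g = g, dx = x)
}

# Batched inference at the model's working resolution (standardized input).
resunet_predict_batch <- function(model, x) {
  resunet_fwd(model@params, model@spec, std_batch(x), training = FALSE)$p
}

count_params <- function(p, skip = c("bn1s", "bn2s")) {
  if (is.list(p)) {
    nm <- names(p)
    keep <- if (is.null(nm)) seq_along(p) else which(!nm %in% skip)
    sum(vapply(p[keep], count_params, numeric(1L)))
  } else length(p)
}

#' @describeIn buildResUNet Trainable parameter count (BN running statistics
#'   excluded).
#' @param model a \linkS4class{ResUNetModel}.
#' @export
setMethod("parameterCount", "ResUNetModel",
          function(model) as.integer(count_params(model@params)))

#' @rdname predictSingle
setMethod("predictSingle", c("ResUNetModel", "Frame"),
  function(model, frame, ...) {
    px <- frame@pixels
    d <- dim(px)
    ws <- model@spec@inputShape
    if (ws[3L] != 3L)
      stop("core expects ", ws[3L], " channels; frames have 3 -- ",
           "use predictTriplet on the extended model")
    native <- c(d[1L], d[2L])
    if (d[1L] != ws[1L] || d[2L] != ws[2L])
      px <- resize_bilinear(px, ws[1L], ws[2L])
    x <- array(px, c(ws[1L], ws[2L], 3L, 1L))
    p <- resunet_predict_batch(model, x)
    p <- array(p, dim(p)[1:2])
    if (!all(native == ws[1:2])) p <- resize_bilinear(p, native[1L], native[2L])
    ProbabilityMap(pmin(pmax(p, 0), 1), t = frame@t, modelTag = model@tag)
  })
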