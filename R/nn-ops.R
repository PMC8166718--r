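# Internal neural-network primitives: forward/backward passes for the layers
# used by the residual U-Net and the 3D-convolution temporal front, the soft
# Dice loss, and Adam. Feature maps are (h, w, c, n) arrays; 3x3 weights are
# (9*c_in, c_out) matrices in im2col order (channel-major, then dx, dy).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

he_w3 <- function(cin, cout) {
  matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
         9L * cin, cout)
}
he_w1 <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
}
he_up <- function(cin, cout) {
  matrix(stats::rnorm(cin * 4L * cout, sd = sqrt(2 / cin)), cin, 4L * cout)
}

## -- 3x3 convolution ---------------------------------------------------------

conv3_fwd <- function(x, W, b, pad = 1L) .cpp_conv3_fwd(x, W, b, as.integer(pad))
conv3_bwd <- function(x, W, dy, pad = 1L) .cpp_conv3_bwd(x, W, dy, as.integer(pad))

## -- 1x1 convolution (channel mixing) ---------------------------------------

conv1_fwd <- function(x, W, b) {
  list(y = .cpp_conv1_fwd(x, W, b), x = x)
}
conv1_bwd <- function(cache, W, dy) .cpp_conv1_bwd(cache$x, W, dy)

## -- batch normalization (per channel over batch and space) ------------------

bn_fwd <- function(x, gamma, beta, rmean, rvar, training) {
  r <- .cpp_bn_fwd(x, gamma, beta, rmean, rvar, training, BN_MOMENTUM,
                   BN_EPS)
  list(y = r$y, cache = list(x = x, mu = r$mu, inv = r$inv, gamma = gamma),
       rmean = r$rmean, rvar = r$rvar)
}

bn_bwd <- function(cache, dy) {
  .cpp_bn_bwd(cache$x, dy, cache$gamma, cache$mu, cache$inv)
}

## -- input standardization ---------------------------------------------------

# Per-sample, per-channel standardization to zero mean / unit sd at the
# gradient models' input. Removes per-video brightness and hue modes so the
# cores learn contrast, not absolute colour; idempotent, so nested calls
# are harmless.
std_batch <- function(x) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  xm <- x; dim(xm) <- c(hw, d[3L] * d[4L])
  mu <- .colMeans(xm, hw, ncol(xm))
  sdv <- sqrt(pmax(.colMeans(xm * xm, hw, ncol(xm)) - mu * mu, 1e-8))
  xm <- (xm - rep(mu, each = hw)) / rep(sdv, each = hw)
  dim(xm) <- d
  xm
}

## -- activations -------------------------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
relu_bwd <- function(mask, dy) dy * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

## -- residual block -----------------------------------------------------------

rb_init <- function(cin, cout, bn = TRUE) {
  p <- list(
    conv1 = list(W = he_w3(cin, cout), b = numeric(cout)),
    conv2 = list(W = he_w3(cout, cout), b = numeric(cout)))
  if (bn) {
    p$bn1 <- list(gamma = rep(1, cout), beta = numeric(cout))
    p$bn2 <- list(gamma = rep(1, cout), beta = numeric(cout))
    p$bn1s <- list(rmean = numeric(cout), rvar = rep(1, cout))
    p$bn2s <- list(rmean = numeric(cout), rvar = rep(1, cout))
  }
  if (cin != cout) p$proj <- list(W = he_w1(cin, cout), b = numeric(cout))
  p
}

# Residual unit: conv-(BN)-relu-conv-(BN) + shortcut, then relu.
# Returns y, a cache for backward, and (in training) updated running stats.
rb_fwd <- function(x, p, bn, training) {
  cache <- list(x = x)
  h <- conv3_fwd(x, p$conv1$W, p$conv1$b)
  if (bn) {
    r <- bn_fwd(h, p$bn1$gamma, p$bn1$beta, p$bn1s$rmean, p$bn1s$rvar,
                training)
    h <- r$y; cache$bn1 <- r$cache
    if (training) { p$bn1s$rmean <- r$rmean; p$bn1s$rvar <- r$rvar }
  }
  r1 <- relu_fwd(h); cache$m1 <- r1$mask; cache$h1 <- r1$y
  h2 <- conv3_fwd(r1$y, p$conv2$W, p$conv2$b)
  if (bn) {
    r <- bn_fwd(h2, p$bn2$gamma, p$bn2$beta, p$bn2s$rmean, p$bn2s$rvar,
                training)
    h2 <- r$y; cache$bn2 <- r$cache
    if (training) { p$bn2s$rmean <- r$rmean; p$bn2s$rvar <- r$rvar }
  }
  if (!is.null(p$proj)) {
    short <- conv1_fwd(x, p$proj$W, p$proj$b)$y
  } else short <- x
  s <- h2 + short
  r2 <- relu_fwd(s); cache$m2 <- r2$mask
  list(y = r2$y, cache = cache, p = p)
}

rb_bwd <- function(p, bn, cache, dy) {
  ds <- relu_bwd(cache$m2, dy)
  g <- list()
  dh2 <- ds
  if (bn) {
    r <- bn_bwd(cache$bn2, dh2)
    dh2 <- r$dx
    g$bn2 <- list(gamma = r$dgamma, beta = r$dbeta)
  }
  r2 <- conv3_bwd(cache$h1, p$conv2$W, dh2)
  g$conv2 <- list(W = r2$dW, b = r2$db)
  dh1 <- relu_bwd(cache$m1, r2$dx)
  if (bn) {
    r <- bn_bwd(cache$bn1, dh1)
    dh1 <- r$dx
    g$bn1 <- list(gamma = r$dgamma, beta = r$dbeta)
  }
  r1 <- conv3_bwd(cache$x, p$conv1$W, dh1)
  g$conv1 <- list(W = r1$dW, b = r1$db)
  dx <- r1$dx
  if (!is.null(p$proj)) {
    pb <- conv1_bwd(list(x = cache$x), p$proj$W, ds)
    g$proj <- list(W = pb$dW, b = pb$db)
    dx <- dx + pb$dx
  } else {
    dx <- dx + ds
  }
  list(dx = dx, g = g)
}

## -- pooling / upsampling -----------------------------------------------------

pool_fwd <- function(x) .cpp_maxpool2_fwd(x)
pool_bwd <- function(dy, arg, dimx) .cpp_maxpool2_bwd(dy, arg, as.integer(dimx))
up_fwd <- function(x, W, b) .cpp_upconv2_fwd(x, W, b)
up_bwd <- function(x, W, dy) .cpp_upconv2_bwd(x, W, dy)

## -- soft Dice loss -----------------------------------------------------------

# Differentiable Dice loss on probabilities: per sample
#   L = 1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)
# which reduces to 1 - 2TP/(2TP + FP + FN) on hard {0,1} maps. Returns the
# batch mean and its gradient w.r.t. p.
soft_dice_loss <- function(p, g, eps = 1e-6) {
  d <- dim(p)
  n <- d[3L]
  dim(p) <- c(d[1L] * d[2L], n)
  dim(g) <- c(d[1L] * d[2L], n)
  spg <- colSums(p * g)
  sp <- colSums(p)
  sg <- colSums(g)
  denom <- sp + sg + eps
  loss <- 1 - (2 * spg + eps) / denom
  # dL/dp_j = -(2 g_j * denom - (2 spg + eps)) / denom^2
  dp <- -(sweep(2 * g, 2L, denom, "*") -
            matrix(2 * spg + eps, nrow(p), n, byrow = TRUE)) /
    matrix(denom^2, nrow(p), n, byrow = TRUE)
  dp <- dp / n
  dim(dp) <- d
  list(loss = mean(loss), per_sample = loss, dp = dp)
}

## -- Adam ---------------------------------------------------------------------

# Parameters and gradients are parallel nested lists of numeric arrays;
# running BN statistics live under names ending in "s" and carry no gradient,
# so the walk is keyed on the gradient structure.
adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else array(0, dim = dim(p) %||% length(p))
  }
  list(m = walk(params), v = walk(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(g)) {
      nms <- names(g)
      for (i in seq_along(g)) {
        k <- if (is.null(nms) || nms[i] == "") i else nms[i]
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    p <- p - lr * mh / (sqrt(vh) + eps)
    list(p = p, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Elementwise sum of two parallel gradient structures (batch accumulation).
grad_add <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- grad_add(a[[i]], b[[i]])
    a
  } else a + b
}

# Exponential moving average of a parameter structure (Polyak averaging;
# evaluation and checkpoints use the averaged weights).
ema_update <- function(e, p, decay) {
  if (is.list(p)) {
    for (i in seq_along(p)) e[[i]] <- ema_update(e[[i]], p[[i]], decay)
    e
  } else decay * e + (1 - decay) * p
}
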