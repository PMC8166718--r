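#' FoldAssignment: patient-wise cross-validation folds
#'
#' @slot folds list of \code{list(train, val)} character vectors of patient
#'   ids; within every fold the two sets are disjoint.
#' @export
setClass("FoldAssignment", representation(folds = "list"))

setValidity("FoldAssignment", function(object) {
  for (f in object@folds)
    if (length(intersect(f$train, f$val)))
      return("train and validation patients overlap within a fold")
  TRUE
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d folds\n", length(object@folds)))
  for (i in seq_along(object@folds))
    cat(sprintf("  fold %d: val = %s\n", i,
                paste(object@folds[[i]]$val, collapse = ", ")))
})

#' Build patient-wise cross-validation folds
#'
#' Each patient is a validation member in exactly one fold; with as many
#' folds as patients this is leave-one-patient-out. Deterministic for a
#' fixed seed.
#'
#' @param patientIds character vector (duplicates collapsed).
#' @param nFolds number of folds (<= number of patients).
#' @param seed shuffling seed.
#' @return A \linkS4class{FoldAssignment}.
#' @examples
#' makePatientFolds(paste0("patient", 1:5), 5, seed = 1)
#' @export
makePatientFolds <- function(patientIds, nFolds = 5L, seed = 1L) {
  pats <- unique(as.character(patientIds))
  if (nFolds > length(pats))
    stop("config error: nFolds (", nFolds, ") exceeds number of patients (",
         length(pats), ")")
  ord <- with_seed(seed, sample(pats))
  grp <- rep(seq_len(nFolds), length.out = length(ord))
  folds <- lapply(seq_len(nFolds), function(k)
    list(train = ord[grp != k], val = ord[grp == k]))
  new("FoldAssignment", folds = folds)
}

#' Verify that no patient crosses a train/validation boundary
#'
#' @param trainData,valData datasets (lists with \code{frames}).
#' @return \code{TRUE} if the patient sets are disjoint (augmented copies
#'   inherit their source frame's patient, so they are covered).
#' @export
checkPatientLeakage <- function(trainData, valData) {
  tr <- unique(vapply(trainData$frames, function(f) f@patientId, ""))
  va <- unique(vapply(valData$frames, function(f) f@patientId, ""))
  length(intersect(tr, va)) == 0L
}

# --- internal data plumbing --------------------------------------------------

frame_pids <- function(data) vapply(data$frames, function(f) f@patientId, "")

subset_data <- function(data, keep) {
  out <- list(frames = data$frames[keep], masks = data$masks[keep])
  if (!is.null(data$manifest)) out$manifest <- data$manifest[keep, ,
                                                             drop = FALSE]
  out
}

# Group frames by video (in temporal order) and form triplets; masks stay
# aligned 1:1 with triplet centers (replicate_edge).
as_triplet_data <- function(data) {
  if (!is.null(data$triplets)) return(data)
  vids <- vapply(data$frames, function(f) f@videoId, "")
  triplets <- list(); masks <- list()
  for (v in unique(vids)) {
    idx <- which(vids == v)
    idx <- idx[order(vapply(data$frames[idx], function(f) f@t, 0L))]
    tr <- makeTriplets(data$frames[idx], "replicate_edge")
    triplets <- c(triplets, tr)
    masks <- c(masks, data$masks[idx])
  }
  list(triplets = triplets, masks = masks)
}

resize_frame_to <- function(f, p, q) {
  if (all(dim(f@pixels)[1:2] == c(p, q))) return(f)
  f@pixels <- resize_bilinear(f@pixels, p, q)
  f
}

resize_mask_to <- function(m, p, q) {
  if (all(dim(m@pixels) == c(p, q))) return(m)
  m@pixels <- (resize_nearest(m@pixels, p, q) >= 0.5) * 1
  m
}

# Chunked inference helpers ---------------------------------------------------

predict_frames_batch <- function(model, frames, chunk = 16L) {
  ws <- model@spec@inputShape
  out <- vector("list", length(frames))
  i <- 1L
  while (i <= length(frames)) {
    idx <- i:min(i + chunk - 1L, length(frames))
    fr <- lapply(frames[idx], resize_frame_to, ws[1L], ws[2L])
    p <- resunet_predict_batch(model, stack_frames(fr))
    for (k in seq_along(idx))
      out[[idx[k]]] <- ProbabilityMap(
        matrix(p[, , k], ws[1L], ws[2L]), t = frames[[idx[k]]]@t,
        modelTag = model@tag)
    i <- i + chunk
  }
  out
}

predict_triplets_batch <- function(model, triplets, chunk = 16L) {
  ws <- model@core@spec@inputShape
  out <- vector("list", length(triplets))
  i <- 1L
  while (i <= length(triplets)) {
    idx <- i:min(i + chunk - 1L, length(triplets))
    tr <- lapply(triplets[idx], function(tp) {
      tp@frames <- lapply(tp@frames, resize_frame_to, ws[1L], ws[2L]); tp
    })
    p <- extended_fwd(model, stack_triplets(tr), training = FALSE)$p
    for (k in seq_along(idx))
      out[[idx[k]]] <- ProbabilityMap(
        matrix(p[, , k], ws[1L], ws[2L]), t = triplets[[idx[k]]]@centerIndex,
        modelTag = model@tag)
    i <- i + chunk
  }
  out
}

# Mean hard DSC of probability maps vs masks at the maps' resolution.
mean_dsc_maps <- function(maps, masks, threshold = 0.5) {
  d <- dim(maps[[1L]]@pixels)
  vals <- vapply(seq_along(maps), function(i) {
    m <- resize_mask_to(masks[[i]], d[1L], d[2L])
    dsc(confusionCounts(binarize(maps[[i]], threshold), m))
  }, 0)
  mean(vals)
}

# --- gradient training -------------------------------------------------------

# Gradient training with optional multi-start: several candidate
# initializations are probed for a couple of epochs and the one with the
# best validation DSC continues (the `nstart` idiom of iterative
# optimizers, guarding against an unlucky initialization basin).
train_gradient_model <- function(model, trainData, valData, lr, bs, epochs,
                                 seed, verbose, extended, inits = 2L,
                                 probeEpochs = 2L, emaDecay = 0.995) {
  if (extended) {
    trainData <- as_triplet_data(trainData)
    valData <- as_triplet_data(valData)
    nTrain <- length(trainData$triplets)
    ws <- model@core@spec@inputShape
  } else {
    nTrain <- length(trainData$frames)
    ws <- model@spec@inputShape
  }
  if (nTrain == 0L) stop("input error: empty training set")
  if (lr < 0) stop("input error: lr must be >= 0")
  stack_in <- function(data, idx) {
    if (extended) {
      tr <- lapply(data$triplets[idx], function(tp) {
        tp@frames <- lapply(tp@frames, resize_frame_to, ws[1L], ws[2L]); tp
      })
      stack_triplets(tr)
    } else {
      std_batch(stack_frames(lapply(data$frames[idx], resize_frame_to,
                                    ws[1L], ws[2L])))
    }
  }
  stack_gt <- function(data, idx)
    stack_masks(lapply(data$masks[idx], resize_mask_to, ws[1L], ws[2L]))
  nVal <- if (extended) length(valData$triplets) else length(valData$frames)
  # cosine decay from the base rate to 5% of it over the epoch budget
  lr_at <- function(ep) lr * (0.05 + 0.95 * 0.5 *
                                (1 + cos(pi * (ep - 1) / max(epochs, 1L))))

  validate <- function(params) {
    if (nVal == 0L) return(c(NA_real_, NA_real_))
    if (extended) { model@front <- params$front
                    model@core@params <- params$core }
    vl <- 0; vd <- 0
    i <- 1L
    while (i <= nVal) {
      idx <- i:min(i + 15L, nVal)
      x <- stack_in(valData, idx)
      g <- stack_gt(valData, idx)
      p <- if (extended) extended_fwd(model, x, training = FALSE)$p
           else resunet_fwd(params, model@spec, x, training = FALSE)$p
      vl <- vl + sum(soft_dice_loss(p, g)$per_sample)
      hard <- (p >= 0.5) * 1
      for (k in seq_along(idx))
        vd <- vd + dsc(confusionCounts(matrix(hard[, , k], ws[1L], ws[2L]),
                                       matrix(g[, , k], ws[1L], ws[2L])))
      i <- i + 16L
    }
    c(vl / nVal, vd / nVal)
  }

  # run `nEpochs` epochs from a state; returns the updated state
  run_epochs <- function(state, nEpochs) {
    params <- state$params; opt <- state$opt
    for (ep in seq_len(nEpochs)) {
      ord <- sample(nTrain)
      epLoss <- 0; nb <- 0L
      for (start in seq(1L, nTrain, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, nTrain)]
        x <- stack_in(trainData, idx)
        g <- stack_gt(trainData, idx)
        if (extended) {
          model@front <- params$front
          model@core@params <- params$core
          fw <- extended_fwd(model, x, training = TRUE)
          params$core <- fw$coreParams
          sd <- soft_dice_loss(fw$p, g)
          model@core@params <- params$core
          grads <- extended_bwd(model, fw, sd$dp)
        } else {
          fw <- resunet_fwd(params, model@spec, x, training = TRUE)
          params <- fw$params
          sd <- soft_dice_loss(fw$p, g)
          grads <- resunet_bwd(params, model@spec, fw$cache, sd$dp)$g
        }
        if (!is.finite(sd$loss))
          stop("divergence error: non-finite loss at epoch ",
               state$epoch + ep, " (lr = ", lr, ")")
        if (lr > 0) {
          st <- adam_step(params, grads, opt, lr_at(state$epoch + ep))
          params <- if (extended)
            list(front = st$params$front, core = st$params$core)
          else st$params
          opt <- st$state
          state$ema <- if (is.null(state$ema)) params
                       else ema_update(state$ema, params, emaDecay)
        }
        epLoss <- epLoss + sd$loss; nb <- nb + 1L
      }
      evalParams <- state$ema %||% params
      vv <- validate(evalParams)
      epoch <- state$epoch + ep
      state$hist <- rbind(state$hist,
                          data.frame(epoch = epoch,
                                     trainLoss = epLoss / nb,
                                     valLoss = vv[1L], valDsc = vv[2L]))
      if (verbose)
        message(sprintf("epoch %d  train %.4f  val %.4f  valDSC %.4f",
                        epoch, epLoss / nb, vv[1L], vv[2L]))
      score <- if (is.na(vv[2L])) -epLoss / nb else vv[2L]
      if (score > state$best$dsc)
        state$best <- list(dsc = score, params = evalParams)
    }
    state$params <- params; state$opt <- opt
    state$epoch <- state$epoch + nEpochs
    state
  }

  init_state <- function(params) {
    list(params = params, opt = adam_init(params), hist = NULL,
         best = list(dsc = -Inf, params = params), epoch = 0L)
  }
  start_params <- if (extended)
    list(front = model@front, core = model@core@params)
  else model@params

  state <- with_seed(seed, {
    if (inits > 1L && epochs > probeEpochs && nVal > 0L) {
      # probe candidate initializations, continue the best
      cands <- list(start_params)
      for (i in 2:inits) {
        cseed <- derive_seed(seed, 9000L + i)
        cands[[i]] <- if (extended) {
          core2 <- buildResUNet(model@core@spec, seed = cseed)
          list(front = frontWeights(model@frontSpec, nC = 3L, init = "he",
                                    seed = cseed),
               core = core2@params)
        } else buildResUNet(model@spec, seed = cseed)@params
      }
      states <- lapply(cands, function(p) run_epochs(init_state(p),
                                                     probeEpochs))
      scores <- vapply(states, function(s) s$best$dsc, 0)
      if (verbose)
        message(sprintf("multi-start probe scores: %s",
                        paste(round(scores, 4), collapse = ", ")))
      run_epochs(states[[which.max(scores)]], epochs - probeEpochs)
    } else {
      run_epochs(init_state(start_params), epochs)
    }
  })

  best <- state$best
  if (extended) {
    model@front <- best$params$front
    model@core@params <- best$params$core
    model@core@trained <- TRUE
  } else {
    model@params <- best$params
    model@trained <- TRUE
  }
  list(model = model, history = state$hist)
}

#' @rdname trainModel
#' @param lr learning rate (Adam).
#' @param bs mini-batch size.
#' @param epochs epoch budget.
#' @param seed seed controlling shuffling (and any stochastic layer).
#' @param verbose print per-epoch progress.
#' @param inits candidate initializations for the multi-start probe
#'   (continues the one with the best validation DSC after
#'   \code{probeEpochs} epochs; 1 disables).
#' @param probeEpochs probe length per candidate.
#' @export
setMethod("trainModel", signature("ResUNetModel"),
  function(model, trainData, valData, lr = 1e-3, bs = 8L, epochs = 15L,
           seed = 1L, verbose = FALSE, inits = 2L, probeEpochs = 2L, ...)
    train_gradient_model(model, trainData, valData, lr, bs, epochs, seed,
                         verbose, extended = FALSE, inits = inits,
                         probeEpochs = probeEpochs))

#' @rdname trainModel
#' @export
setMethod("trainModel", signature("ExtendedModel"),
  function(model, trainData, valData, lr = 1e-3, bs = 8L, epochs = 15L,
           seed = 1L, verbose = FALSE, inits = 2L, probeEpochs = 2L, ...) {
    if (is(model@core, "ResUNetModel"))
      train_gradient_model(model, trainData, valData, lr, bs, epochs, seed,
                           verbose, extended = TRUE, inits = inits,
                           probeEpochs = probeEpochs)
    else
      train_instance_extended(model, trainData, valData, seed = seed)
  })

# Sweep the proposal generator's tunables + confidence for the instance core.
instance_sweep <- function(frames_px, masks, spec, params, maxFrames,
                           seed) {
  idx <- seq_along(frames_px)
  if (length(idx) > maxFrames)
    idx <- with_seed(seed, sort(sample(idx, maxFrames)))
  grid <- expand.grid(sigma = c(1, 2, 3),
                      confidence = seq(0.5, 0.9, by = 0.1))
  best <- NULL; bestDsc <- -Inf; tab <- NULL
  for (r in seq_len(nrow(grid))) {
    pr <- params; pr$sigma <- grid$sigma[r]
    vals <- vapply(idx, function(i) {
      ins <- propose_instances(frames_px[[i]], pr, spec@anchorScales)
      mp <- instancesToLumenMap(ins$masks, ins$scores,
                                confidenceThreshold = grid$confidence[r],
                                mergePolicy = pr$mergePolicy)
      dsc(confusionCounts(binarize(mp, 0.5), masks[[i]]@pixels))
    }, 0)
    m <- mean(vals)
    tab <- rbind(tab, data.frame(sigma = grid$sigma[r],
                                 confidence = grid$confidence[r], dsc = m))
    if (m > bestDsc + 1e-12) {
      bestDsc <- m
      best <- list(sigma = grid$sigma[r], confidence = grid$confidence[r])
    }
  }
  list(best = best, table = tab)
}

#' @rdname trainModel
#' @param maxFrames cap on frames scored per sweep point (deterministic
#'   subsample) to bound the classical core's fitting cost.
#' @export
setMethod("trainModel", signature("InstanceSegModel"),
  function(model, trainData, valData, seed = 1L, maxFrames = 60L, ...) {
    if (!length(trainData$frames)) stop("input error: empty training set")
    sw <- instance_sweep(lapply(trainData$frames, slot, "pixels"),
                         trainData$masks, model@spec, model@params,
                         maxFrames, seed)
    model@params$sigma <- sw$best$sigma
    model@spec@minDetectionConfidence <- sw$best$confidence
    model@trained <- TRUE
    list(model = model, history = sw$table)
  })

train_instance_extended <- function(model, trainData, valData, seed = 1L,
                                    maxFrames = 60L, ...) {
  trainData <- as_triplet_data(trainData)
  if (!length(trainData$triplets)) stop("input error: empty training set")
  # push triplets through the (fixed, temporal-mean initialized) front and
  # fit the core's tunables on the resulting pseudo-frames
  px <- lapply(trainData$triplets, function(tp) {
    fw <- front_fwd(stack_triplet(tp), model@front$W, model@front$b,
                    model@frontSpec@activation)
    pmin(pmax(array(fw$y, dim(fw$y)[1:3]), 0), 1)
  })
  sw <- instance_sweep(px, trainData$masks, model@core@spec,
                       model@core@params, maxFrames, seed)
  model@core@params$sigma <- sw$best$sigma
  model@core@spec@minDetectionConfidence <- sw$best$confidence
  model@core@trained <- TRUE
  list(model = model, history = sw$table)
}

# --- grid search -------------------------------------------------------------

#' Hyperparameter grid search under patient-wise cross-validation
#'
#' Trains every hyperparameter combination on every fold and selects the
#' combination with the highest mean validation DSC; ties are broken by the
#' smaller learning rate, then the smaller batch size. The default search
#' space is learning rates \{1e-3, 1e-4, 1e-5, 1e-6\} crossed with batch
#' sizes \{4, 8, 16\}; an \code{n_k_options} axis is added for the
#' multi-frame residual U-Net.
#'
#' @param space list with \code{learning_rates}, \code{batch_sizes} and
#'   optionally \code{n_k_options}.
#' @param folds a \linkS4class{FoldAssignment}.
#' @param data training dataset (frames/masks with patient provenance).
#' @param buildFn \code{function(lr, bs, nK, seed)} returning a fresh model
#'   (the \code{nK} argument may be ignored for single-frame families).
#' @param epochs,seed training settings applied to every run.
#' @param verbose print progress.
#' @return list with \code{best} (named list lr, bs, nK) and
#'   \code{cvTable} (one row per combination x fold); the selection is
#'   re-derivable from the table alone.
#' @export
gridSearch <- function(space, folds, data, buildFn, epochs = 5L, seed = 1L,
                       verbose = FALSE) {
  stopifnot(is(folds, "FoldAssignment"))
  lrs <- space$learning_rates
  bss <- space$batch_sizes
  nks <- space$n_k_options
  if (!length(lrs) || !length(bss))
    stop("config error: empty search space")
  combos <- expand.grid(lr = lrs, bs = bss,
                        nK = if (is.null(nks)) NA else nks)
  pid <- frame_pids(data)
  tab <- NULL
  for (ci in seq_len(nrow(combos))) {
    for (fi in seq_along(folds@folds)) {
      f <- folds@folds[[fi]]
      tr <- subset_data(data, pid %in% f$train)
      va <- subset_data(data, pid %in% f$val)
      if (!length(tr$frames))
        stop("config error: fold ", fi, " has an empty training set")
      model <- buildFn(lr = combos$lr[ci], bs = combos$bs[ci],
                       nK = combos$nK[ci], seed = derive_seed(seed, ci))
      # one shuffling stream per fold: combos see identical data order
      # (paired comparisons across the grid)
      fit <- trainModel(model, tr, va, lr = combos$lr[ci],
                        bs = combos$bs[ci], epochs = epochs,
                        seed = derive_seed(seed, fi))
      vd <- if (!is.null(fit$history$valDsc))
        max(fit$history$valDsc, na.rm = TRUE)
      else max(fit$history$dsc, na.rm = TRUE)
      tab <- rbind(tab, data.frame(combo = ci, fold = fi,
                                   lr = combos$lr[ci], bs = combos$bs[ci],
                                   nK = combos$nK[ci], valDsc = vd))
      if (verbose)
        message(sprintf("combo %d fold %d: valDSC %.4f", ci, fi, vd))
    }
  }
  aggv <- tapply(tab$valDsc, tab$combo, mean)
  agg <- merge(data.frame(combo = as.integer(names(aggv)),
                          valDsc = as.numeric(aggv)),
               unique(tab[c("combo", "lr", "bs", "nK")]), by = "combo")
  ord <- order(-agg$valDsc, agg$lr, agg$bs)
  bestRow <- agg[ord[1L], ]
  list(best = list(lr = bestRow$lr, bs = bestRow$bs,
                   nK = if (is.na(bestRow$nK)) NULL else bestRow$nK,
                   valDsc = bestRow$valDsc),
       cvTable = tab)
}

# --- final fit and ablation --------------------------------------------------

#' Frame-random 60/40 split stratified by video
#'
#' @param data dataset.
#' @param splitRatio training fraction, in \code{(0, 1)}; 1.0 is rejected
#'   because checkpoint selection needs a validation set.
#' @param seed shuffling seed.
#' @param patientWise if \code{TRUE}, split whole patients instead of
#'   frames.
#' @return list with \code{train} and \code{val} datasets.
#' @export
splitTrainVal <- function(data, splitRatio = 0.6, seed = 1L,
                          patientWise = FALSE) {
  if (splitRatio <= 0 || splitRatio >= 1)
    stop("config error: splitRatio must lie strictly between 0 and 1")
  n <- length(data$frames)
  if (patientWise) {
    pid <- frame_pids(data)
    pats <- unique(pid)
    ntr <- max(1L, round(splitRatio * length(pats)))
    trP <- with_seed(seed, sample(pats, ntr))
    keep <- pid %in% trP
  } else {
    vids <- vapply(data$frames, function(f) f@videoId, "")
    keep <- logical(n)
    with_seed(seed, {
      for (v in unique(vids)) {
        idx <- which(vids == v)
        ntr <- round(splitRatio * length(idx))
        keep[sample(idx, ntr)] <- TRUE
      }
    })
  }
  list(train = subset_data(data, keep), val = subset_data(data, !keep))
}

#' Final fit of every ensemble member with selected hyperparameters
#'
#' Splits the training patients' frames 60/40 (train/validation), trains
#' each supplied member model with its hyperparameters, and returns the four
#' checkpoints that feed the ensemble.
#'
#' @param models named list of untrained member models (tags as names).
#' @param bestParams named list per member: \code{list(lr, bs)} (gradient
#'   models; ignored by the instance core).
#' @param data all frames of the training patients.
#' @param splitRatio training fraction (default 0.6).
#' @param epochs epoch budget per member.
#' @param seed master seed.
#' @param verbose print progress.
#' @return named list per member: \code{list(model, history)}.
#' @export
finalFit <- function(models, bestParams, data, splitRatio = 0.6,
                     epochs = 15L, seed = 1L, verbose = FALSE) {
  sp <- splitTrainVal(data, splitRatio, seed = seed)
  out <- list()
  for (tag in names(models)) {
    bp <- bestParams[[tag]]
    if (is.null(bp) && (is(models[[tag]], "ResUNetModel") ||
                        (is(models[[tag]], "ExtendedModel") &&
                         is(models[[tag]]@core, "ResUNetModel"))))
      stop("order-of-operations error: no hyperparameters for member ", tag,
           " -- run gridSearch first")
    out[[tag]] <- trainModel(models[[tag]], sp$train, sp$val,
                             lr = bp$lr %||% 1e-3, bs = bp$bs %||% 8L,
                             epochs = epochs, seed = derive_seed(seed,
                                                                 match(tag,
                                                                       names(models))),
                             verbose = verbose)
  }
  out
}

#' Ablation suite: singles, member pairs, and the full ensemble
#'
#' Evaluates each single model, the four two-member ensembles
#' (m1,m2), (M1,M2), (M1,m1), (M2,m2) and the full 4-member ensemble on a
#' held-out test set, all through the same fusion code path. Member
#' probability maps are computed once per frame and reused across
#' configurations. Returns the per-frame metric rows and Kruskal--Wallis
#' comparisons of the single models' per-frame DSC.
#'
#' @param models named list with entries \code{m1}, \code{m2}, \code{M1},
#'   \code{M2}.
#' @param testData held-out dataset.
#' @param threshold binarization threshold.
#' @param configs list of character vectors naming the member subsets to
#'   evaluate (defaults to the standard 9).
#' @return list with \code{perFrame} (data.frame), \code{summary},
#'   \code{comparison}.
#' @export
runAblation <- function(models, testData, threshold = 0.5,
                        configs = NULL) {
  need <- c("m1", "m2", "M1", "M2")
  if (!all(need %in% names(models)))
    stop("dependency error: missing checkpoint(s): ",
         paste(setdiff(need, names(models)), collapse = ", "))
  if (is.null(configs))
    configs <- c(as.list(need),
                 list(c("m1", "m2"), c("M1", "M2"), c("M1", "m1"),
                      c("M2", "m2"), need))
  for (cf in configs)
    if (anyDuplicated(cf))
      stop("config error: ensemble members must be unique (got ",
           paste(cf, collapse = ","), ")")
  td <- as_triplet_data(testData)
  # member maps once per frame
  memberMaps <- list(
    m1 = predict_frames_batch(models$m1,
                              lapply(td$triplets,
                                     function(tp) tp@frames[[2L]])),
    M1 = predict_triplets_batch(models$M1, td$triplets),
    m2 = lapply(td$triplets, function(tp)
      predictSingle(models$m2, tp@frames[[2L]])),
    M2 = lapply(td$triplets, function(tp)
      predictTriplet(models$M2, tp)))
  # unify map resolutions to the mask resolution per frame
  d0 <- dim(td$masks[[1L]]@pixels)
  for (tag in names(memberMaps))
    memberMaps[[tag]] <- lapply(memberMaps[[tag]], function(mp) {
      if (!all(dim(mp@pixels) == d0))
        mp <- ProbabilityMap(pmin(pmax(resize_bilinear(mp@pixels, d0[1L],
                                                       d0[2L]), 0), 1),
                             t = mp@t, modelTag = mp@modelTag)
      mp
    })
  perFrame <- NULL
  dscLists <- list()
  for (cf in configs) {
    tag <- paste(cf, collapse = "+")
    rows <- lapply(seq_along(td$triplets), function(i) {
      fused <- ensemblePredict(lapply(cf, function(m) memberMaps[[m]][[i]]),
                               modelTag = tag)
      evaluateFrame(binarize(fused, threshold), td$masks[[i]], tag)
    })
    rows <- do.call(rbind, rows)
    rows$t <- vapply(td$triplets, function(tp) tp@centerIndex, 0L)
    perFrame <- rbind(perFrame, rows)
    if (length(cf) == 1L) dscLists[[tag]] <- rows$dsc
  }
  comparison <- if (length(dscLists) >= 2L &&
                    all(lengths(dscLists) >= 2L)) compareModels(dscLists)
                else NULL
  list(perFrame = perFrame, summary = aggregateMetrics(perFrame),
       comparison = comparison)
}
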