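#' Pixel confusion counts between a predicted and a reference mask
#'
#' Standard definitions: TP are pixels foreground in both masks, FP
#' foreground only in the prediction, FN foreground only in the reference,
#' TN the remainder; the four counts always sum to p*q.
#'
#' @param pred,truth \linkS4class{BinaryMask} objects or 0/1 matrices of
#'   identical shape.
#' @return A \linkS4class{ConfusionCounts}.
#' @examples
#' a <- matrix(0, 8, 8); a[1:5, 1:2] <- 1
#' confusionCounts(a, a)
#' @export
confusionCounts <- function(pred, truth) {
  p <- if (is(pred, "BinaryMask")) pred@pixels else pred
  g <- if (is(truth, "BinaryMask")) truth@pixels else truth
  if (!all(dim(p) == dim(g)))
    stop("alignment error: mask shapes differ")
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  ConfusionCounts(tp = tp, fp = fp, fn = fn,
                  tn = length(p) - tp - fp - fn)
}

#' Dice loss from confusion counts
#'
#' \deqn{L_{DSC} = 1 - \frac{2TP}{2TP + FN + FP}.}
#' When TP, FP and FN are all zero (both masks empty) the loss is 0 by
#' convention: agreement on absence is perfect agreement.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return numeric in \code{[0, 1]}.
#' @examples
#' diceLoss(ConfusionCounts(tp = 6, fp = 2, fn = 2, tn = 54))  # 0.25
#' @export
diceLoss <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  validObject(counts)
  denom <- 2 * counts@tp + counts@fn + counts@fp
  if (denom == 0) return(0)
  1 - 2 * counts@tp / denom
}

#' Dice similarity coefficient (the complement of the Dice loss)
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return numeric in \code{[0, 1]}.
#' @export
dsc <- function(counts) 1 - diceLoss(counts)

#' Differentiable soft Dice loss on a probability map
#'
#' The training variant of the Dice loss: hard counts are replaced by sums
#' of products of probabilities and reference values, with a smoothing
#' epsilon in numerator and denominator so the empty-empty case is defined
#' and gradients stay finite. Evaluation always uses hard counts.
#'
#' @param prob a \linkS4class{ProbabilityMap} or numeric matrix in
#'   \code{[0, 1]}.
#' @param truth a \linkS4class{BinaryMask} or 0/1 matrix.
#' @param eps smoothing constant (default 1e-6, small enough not to perturb
#'   the third decimal at 64 x 64).
#' @return numeric loss.
#' @export
softDiceLoss <- function(prob, truth, eps = 1e-6) {
  p <- if (is(prob, "ProbabilityMap")) prob@pixels else prob
  g <- if (is(truth, "BinaryMask")) truth@pixels else truth
  if (!all(dim(p) == dim(g)))
    stop("alignment error: shapes differ")
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

#' Evaluate one predicted mask against the reference
#'
#' Computes the Dice similarity coefficient, precision and recall from the
#' frame's confusion counts:
#' DSC = 1 - L_DSC, Prec = TP/(TP+FP), Rec = TP/(TP+FN).
#' Degenerate denominators follow the documented convention: an empty
#' prediction has precision 1 if the reference is also empty and 0
#' otherwise, and symmetrically for recall; the empty-empty frame scores
#' 1 on all three metrics.
#'
#' @param pred,truth \linkS4class{BinaryMask} objects or 0/1 matrices.
#' @param modelTag tag recorded in the output row.
#' @return one-row \code{data.frame} with columns \code{t}, \code{model},
#'   \code{dsc}, \code{precision}, \code{recall}.
#' @examples
#' g <- matrix(0, 4, 4); g[1:2, 1:4] <- 1                 # 8 true pixels
#' p <- matrix(0, 4, 4); p[1:2, 1:3] <- 1; p[3, 1:2] <- 1  # TP=6 FP=2 FN=2
#' evaluateFrame(p, g)  # dsc = precision = recall = 0.75
#' @export
evaluateFrame <- function(pred, truth, modelTag = "model") {
  cc <- confusionCounts(pred, truth)
  prec <- if (cc@tp + cc@fp == 0) as.numeric(cc@fn == 0)
          else cc@tp / (cc@tp + cc@fp)
  rec <- if (cc@tp + cc@fn == 0) as.numeric(cc@fp == 0)
         else cc@tp / (cc@tp + cc@fn)
  tt <- if (is(pred, "BinaryMask")) pred@t else 0L
  data.frame(t = tt, model = modelTag, dsc = dsc(cc), precision = prec,
             recall = rec)
}

#' Evaluate parallel lists of predictions and references
#'
#' @param preds,truths parallel lists of masks.
#' @param modelTag tag recorded on every row.
#' @return \code{data.frame}, one row per frame.
#' @export
evaluateFrames <- function(preds, truths, modelTag = "model") {
  stopifnot(length(preds) == length(truths))
  do.call(rbind, lapply(seq_along(preds), function(i) {
    row <- evaluateFrame(preds[[i]], truths[[i]], modelTag)
    row$t <- if (is(preds[[i]], "BinaryMask")) preds[[i]]@t else i - 1L
    row
  }))
}

#' Compare per-frame DSC distributions across models (Kruskal--Wallis)
#'
#' Omnibus Kruskal--Wallis test across all models plus pairwise tests with
#' significance stars at the 0.05 / 0.01 / 0.001 levels.
#'
#' @param perFrameDsc named list: model tag -> numeric vector of per-frame
#'   DSC values (each of length >= 2).
#' @return list with \code{H}, \code{p}, \code{df} and a \code{pairwise}
#'   data.frame (columns \code{a}, \code{b}, \code{p}, \code{stars}).
#' @examples
#' compareModels(list(a = c(.7, .8, .9), b = c(.2, .3, .4)))$pairwise
#' @export
compareModels <- function(perFrameDsc) {
  if (length(perFrameDsc) < 2L)
    stop("input error: need at least 2 models to compare")
  if (any(lengths(perFrameDsc) < 2L))
    stop("input error: each model needs at least 2 frames")
  kw <- stats::kruskal.test(perFrameDsc)
  tags <- names(perFrameDsc)
  pw <- NULL
  for (i in seq_len(length(tags) - 1L))
    for (j in (i + 1L):length(tags)) {
      pk <- stats::kruskal.test(perFrameDsc[c(i, j)])$p.value
      pw <- rbind(pw, data.frame(a = tags[i], b = tags[j], p = pk,
                                 stars = sig_stars(pk)))
    }
  list(H = unname(kw$statistic), p = kw$p.value,
       df = unname(kw$parameter), pairwise = pw)
}

sig_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Aggregate per-frame metrics per model
#'
#' Frame-mean metrics plus distribution quartiles of the DSC (the box-plot
#' summary), per model.
#'
#' @param df data.frame as produced by \code{\link{evaluateFrames}}.
#' @return data.frame with one row per model.
#' @export
aggregateMetrics <- function(df) {
  do.call(rbind, lapply(split(df, df$model), function(s) {
    qs <- stats::quantile(s$dsc, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(model = s$model[1L], n = nrow(s), dsc = mean(s$dsc),
               precision = mean(s$precision), recall = mean(s$recall),
               dsc_q1 = qs[1L], dsc_median = qs[2L], dsc_q3 = qs[3L])
  }))
}

#' Confusion overlay image for visual inspection
#'
#' Colors each pixel by its confusion class: TP yellow, FP pink, FN blue,
#' TN black.
#'
#' @param pred,truth \linkS4class{BinaryMask} objects or 0/1 matrices.
#' @return a \code{p x q x 3} RGB array.
#' @export
overlayConfusion <- function(pred, truth) {
  p <- if (is(pred, "BinaryMask")) pred@pixels else pred
  g <- if (is(truth, "BinaryMask")) truth@pixels else truth
  if (!all(dim(p) == dim(g))) stop("alignment error: mask shapes differ")
  out <- array(0, c(dim(p), 3L))
  tp <- p == 1 & g == 1; fp <- p == 1 & g == 0; fn <- p == 0 & g == 1
  r <- matrix(0, nrow(p), ncol(p)); gg <- r; b <- r
  r[tp] <- 1; gg[tp] <- 1          # yellow
  r[fp] <- 1; gg[fp] <- 0.6; b[fp] <- 0.8  # pink
  b[fn] <- 1                        # blue
  out[, , 1L] <- r; out[, , 2L] <- gg; out[, , 3L] <- b
  out
}

#' Write an evaluation report (CSV + JSON summary)
#'
#' @param df per-frame metrics data.frame.
#' @param dir output directory (created if missing).
#' @param pairwise optional result of \code{\link{compareModels}}.
#' @return invisibly, the paths written.
#' @export
writeEvaluationReport <- function(df, dir, pairwise = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "per_frame_metrics.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  summ <- list(perModel = aggregateMetrics(df))
  if (!is.null(pairwise)) summ$comparison <- pairwise
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv, js))
}
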