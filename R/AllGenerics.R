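#' Segment a single frame with a single-frame core model
#'
#' Runs a core model (residual U-Net or the instance core) on one frame and
#' returns the per-pixel lumen probability map at the frame's native
#' resolution. If the model's working resolution differs from the frame's,
#' the frame is resized (bilinear) for inference and the prediction resized
#' back before it is returned.
#'
#' @param model a trained or untrained core model handle.
#' @param frame a \linkS4class{Frame}.
#' @param ... method-specific arguments.
#' @return A \linkS4class{ProbabilityMap} with the frame's \code{t}.
#' @export
setGeneric("predictSingle",
           function(model, frame, ...) standardGeneric("predictSingle"))

#' Segment the central frame of a triplet with a multi-frame model
#'
#' @param model an \linkS4class{ExtendedModel}.
#' @param triplet a \linkS4class{FrameTriplet}.
#' @param ... method-specific arguments.
#' @return A \linkS4class{ProbabilityMap} indexed by the triplet's center.
#' @export
setGeneric("predictTriplet",
           function(model, triplet, ...) standardGeneric("predictTriplet"))

#' Train a segmentation model on frames and masks
#'
#' For the gradient-based models (residual U-Net and its temporal extension)
#' this minimizes the soft Dice loss with Adam, records per-epoch train/val
#' loss and validation DSC, and retains the weights of the epoch with the
#' best validation DSC. For the instance core it sweeps the proposal
#' generator's tunables and the minimal detection confidence, selecting the
#' combination with the highest training DSC.
#'
#' @param model a model handle.
#' @param trainData,valData datasets as returned by
#'   \code{\link{generateDataset}} (lists with \code{frames}, \code{masks}),
#'   or lists with those fields.
#' @param ... training settings: \code{lr}, \code{bs}, \code{epochs},
#'   \code{seed}, \code{verbose}.
#' @return A list with \code{model} (best checkpoint) and \code{history}
#'   (data.frame of per-epoch train loss, val loss, val DSC).
#' @export
setGeneric("trainModel",
           function(model, trainData, valData, ...)
             standardGeneric("trainModel"))

#' Number of trainable parameters of a model
#' @param model a model handle.
#' @return Integer parameter count.
#' @export
setGeneric("parameterCount",
           function(model) standardGeneric("parameterCount"))
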