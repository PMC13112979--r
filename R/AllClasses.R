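# S4 containers for the user-facing objects: synthetic dataset
# specification, dataset manifest, model, training history and evaluation
# report.

#' @importFrom utils head write.csv read.csv
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Synthetic fundus dataset specification
#'
#' @slot nImages number of images to generate.
#' @slot imageSize square image side in pixels (>= 32).
#' @slot classProportions length-5 non-negative vector summing to 1.
#' @slot lesionModel per-grade lesion parameters (see [lesionModel()]).
#' @slot noiseSd Gaussian pixel-noise standard deviation.
#' @slot seed integer generator seed.
#' @export
setClass("FundusSpec", representation(
  nImages = "integer", imageSize = "integer",
  classProportions = "numeric", lesionModel = "list",
  noiseSd = "numeric", seed = "integer"))

setValidity("FundusSpec", function(object) {
  msgs <- character()
  if (object@nImages < 1L) msgs <- c(msgs, "nImages must be positive")
  if (object@imageSize < 32L) msgs <- c(msgs, "imageSize must be >= 32")
  p <- object@classProportions
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-6)
    msgs <- c(msgs, "classProportions must be 5 non-negative values summing to 1")
  lm <- object@lesionModel
  dots <- vapply(lm, function(g) g$dots[2L], numeric(1L))
  blobs <- vapply(lm, function(g) g$blobs[2L], numeric(1L))
  if (any(diff(dots) < 0) || any(diff(blobs) < 0))
    msgs <- c(msgs, "lesion count ranges must be monotone in grade")
  if (lm[[1L]]$dots[2L] != 0 || lm[[1L]]$blobs[2L] != 0)
    msgs <- c(msgs, "grade 0 must have zero lesions")
  if (length(msgs)) msgs else TRUE
})

#' Dataset manifest
#'
#' Carries the id/label table (APTOS CSV dialect: `id_code`, `diagnosis`),
#' plus either in-memory images or the directory their PNGs live in.
#'
#' @slot records data.frame with columns `id_code`, `diagnosis`.
#' @slot images optional named list of in-memory `(H, W, 3)` arrays.
#' @slot dir directory containing `<id_code>.png` files ("" if in-memory).
#' @slot split one of "train", "test", "none".
#' @export
setClass("FundusManifest", representation(
  records = "data.frame", images = "listOrNULL",
  dir = "character", split = "character"))

setValidity("FundusManifest", function(object) {
  r <- object@records
  msgs <- character()
  if (!all(c("id_code", "diagnosis") %in% names(r)))
    msgs <- c(msgs, "records must have id_code and diagnosis columns")
  else {
    if (anyDuplicated(r$id_code)) msgs <- c(msgs, "id_code values must be unique")
    if (any(r$diagnosis < 0L | r$diagnosis > 4L))
      msgs <- c(msgs, "diagnosis must be in 0..4")
  }
  if (!object@split %in% c("train", "test", "none"))
    msgs <- c(msgs, "split must be train/test/none")
  if (length(msgs)) msgs else TRUE
})

#' Dual-head grading model
#'
#' @slot params nested list of trainable arrays.
#' @slot config model configuration (backbone preset, SPM, lesion
#'   attention, heads).
#' @slot prompts clinical prompt strings.
#' @slot promptEmbeddings K' x D matrix of prompt embeddings.
#' @slot encoder prior-encoder contract (list with `embedImage`,
#'   `embedTexts`, `name`).
#' @slot seed integer initialisation seed.
#' @export
setClass("GraderModel", representation(
  params = "list", config = "list", prompts = "character",
  promptEmbeddings = "matrix", encoder = "list", seed = "integer"))

#' Training history
#'
#' @slot log per-epoch data.frame (epoch, lr, trainLoss, valLoss,
#'   valAccuracy, valQWK).
#' @slot bestEpoch epoch index with the best validation QWK.
#' @export
setClass("TrainHistory", representation(
  log = "data.frame", bestEpoch = "integer"))

setValidity("TrainHistory", function(object) {
  if (nrow(object@log) > 0 &&
      (object@bestEpoch < 1L || object@bestEpoch > nrow(object@log)))
    "bestEpoch out of range" else TRUE
})

#' Evaluation report
#'
#' @slot accuracy exact-match accuracy in [0,1].
#' @slot qwk quadratic weighted kappa in [-1,1].
#' @slot perClassAUC one-vs-rest AUC per class (NA when undefined).
#' @slot microAUC pooled one-vs-rest AUC.
#' @slot macroAUC unweighted mean of defined per-class AUCs.
#' @slot confusion K x K counts matrix (rows true, columns predicted).
#' @export
setClass("EvalReport", representation(
  accuracy = "numeric", qwk = "numeric", perClassAUC = "numeric",
  microAUC = "numeric", macroAUC = "numeric", confusion = "matrix"))

setValidity("EvalReport", function(object) {
  msgs <- character()
  if (object@accuracy < 0 || object@accuracy > 1)
    msgs <- c(msgs, "accuracy must lie in [0,1]")
  if (!is.na(object@qwk) && (object@qwk < -1 - 1e-9 || object@qwk > 1 + 1e-9))
    msgs <- c(msgs, "qwk must lie in [-1,1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FundusSpec", function(object) {
  cat(sprintf("FundusSpec: %d images, %dx%d px, noise sd %.3f, seed %d\n",
              object@nImages, object@imageSize, object@imageSize,
              object@noiseSd, object@seed))
  cat("  class proportions:",
      paste(sprintf("%.3f", object@classProportions), collapse = " "), "\n")
})

setMethod("show", "FundusManifest", function(object) {
  tab <- table(factor(object@records$diagnosis, levels = 0:4))
  cat(sprintf("FundusManifest (%s): %d samples (%s)\n", object@split,
              nrow(object@records),
              if (is.null(object@images)) object@dir else "in-memory"))
  cat("  grade counts:", paste(as.integer(tab), collapse = " "), "\n")
})

setMethod("show", "GraderModel", function(object) {
  cat(sprintf("GraderModel: %s backbone, %s parameters\n",
              object@config$backbone$preset,
              format(countParams(object), big.mark = ",")))
  cat(sprintf("  semantic prior: %s | lesion attention: %s | K = %d\n",
              if (isTRUE(object@config$spm$enabled))
                sprintf("on (%d prompts, tau=%.2f)", length(object@prompts),
                        object@config$spm$temperature) else "off",
              if (isTRUE(object@config$plka$enabled)) "on" else "off",
              object@config$K))
})

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf("TrainHistory: %d epochs, best epoch %d (val QWK %.4f)\n",
              nrow(object@log), object@bestEpoch,
              object@log$valQWK[object@bestEpoch]))
  print(head(object@log, 5L))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.4f | QWK %.4f | micro AUC %.4f | macro AUC %.4f\n",
              object@accuracy, object@qwk, object@microAUC, object@macroAUC))
  cat("  per-class AUC:",
      paste(sprintf("%.3f", object@perClassAUC), collapse = " "), "\n")
})

# ---- accessors -------------------------------------------------------------

#' Manifest label table
#' @param manifest a `FundusManifest`.
#' @return data.frame with `id_code`, `diagnosis`.
#' @export
manifestTable <- function(manifest) manifest@records

#' Number of samples in a manifest
#' @param manifest a `FundusManifest`.
#' @return integer count.
#' @export
nSamples <- function(manifest) nrow(manifest@records)

#' Model configuration
#' @param model a `GraderModel`.
#' @return configuration list.
#' @export
modelConfig <- function(model) model@config

#' History log table
#' @param history a `TrainHistory`.
#' @return per-epoch data.frame.
#' @export
historyLog <- function(history) history@log

#' Report metrics as a plain list
#' @param report an `EvalReport`.
#' @return list with accuracy, qwk, perClassAUC, microAUC, macroAUC,
#'   confusion.
#' @export
reportMetrics <- function(report) {
  list(accuracy = report@accuracy, qwk = report@qwk,
       perClassAUC = report@perClassAUC, microAUC = report@microAUC,
       macroAUC = report@macroAUC, confusion = report@confusion)
}
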