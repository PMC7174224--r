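#' @import methods
#' @importFrom stats rnorm runif sd var quantile setNames qtukey ptukey uniroot pf aov anova predict
#' @importFrom utils head tail write.csv read.csv
NULL

SAFFRON_CLASSES <- c("Pushal", "Negin", "Sargol")

#' Saffron commercial class labels
#'
#' The fixed ordering of the three Iranian commercial saffron grades used
#' throughout the package: \code{"Pushal"} (joined filament triplets carrying
#' a small amount of yellow style), \code{"Negin"} (long, intact, separated
#' red filaments) and \code{"Sargol"} (short broken red fragments).
#'
#' @return Character vector of length 3.
#' @export
#' @examples
#' saffronClasses()
saffronClasses <- function() SAFFRON_CLASSES

#' SceneParams: parameters of a synthetic bulk-saffron scene
#'
#' Describes one synthetic image of bulk saffron threads on a near-black
#' background: how many filaments to render, their geometry, the target
#' fraction of yellow style pixels among foreground pixels, colors, and the
#' imaging imperfections (illumination gradient, sensor noise).
#'
#' @slot classLabel one of \code{saffronClasses()}.
#' @slot nFilaments positive integer, number of filament units rendered.
#' @slot filamentLength numeric length-2 range (pixels) of filament lengths.
#' @slot filamentWidth numeric length-2 range (pixels) of filament widths;
#'   must lie strictly below the length range (a filament is elongated).
#' @slot breakProbability probability that a filament is rendered as a broken
#'   fragment (a random sub-segment of its spine); high for Sargol.
#' @slot tripletJoin logical; if \code{TRUE} filaments are drawn in groups of
#'   three sharing a base point, as in Pushal.
#' @slot styleFraction target fraction of foreground pixels rendered in the
#'   yellow style color, in [0, 1].
#' @slot stigmaColor,styleColor RGB triples in 0..255 (dark red / yellow).
#' @slot backgroundLevel integer background gray level, must be <= 20 so the
#'   intensity-threshold segmentation can separate the background.
#' @slot noiseSd standard deviation of additive Gaussian sensor noise.
#' @slot illuminationGradient relative brightness falloff across the canvas,
#'   in [0, 1].
#' @slot width,height canvas size in pixels (>= 256 each).
#' @slot seed integer seed; identical parameters (including the seed) yield
#'   bit-identical images.
#' @seealso [sceneParams()], [generateImage()]
#' @export
setClass("SceneParams", representation(
  classLabel = "character",
  nFilaments = "integer",
  filamentLength = "numeric",
  filamentWidth = "numeric",
  breakProbability = "numeric",
  tripletJoin = "logical",
  styleFraction = "numeric",
  stigmaColor = "numeric",
  styleColor = "numeric",
  backgroundLevel = "integer",
  noiseSd = "numeric",
  illuminationGradient = "numeric",
  width = "integer",
  height = "integer",
  seed = "integer"
))

setValidity("SceneParams", function(object) {
  msg <- character()
  if (!object@classLabel %in% SAFFRON_CLASSES)
    msg <- c(msg, sprintf("classLabel must be one of %s",
                          paste(SAFFRON_CLASSES, collapse = ", ")))
  if (object@nFilaments < 1L) msg <- c(msg, "nFilaments must be >= 1")
  if (length(object@filamentLength) != 2L || any(object@filamentLength <= 0) ||
      diff(object@filamentLength) < 0)
    msg <- c(msg, "filamentLength must be a nondecreasing positive range")
  if (length(object@filamentWidth) != 2L || any(object@filamentWidth <= 0) ||
      diff(object@filamentWidth) < 0)
    msg <- c(msg, "filamentWidth must be a nondecreasing positive range")
  if (length(object@filamentWidth) == 2L && length(object@filamentLength) == 2L &&
      max(object@filamentWidth) >= min(object@filamentLength))
    msg <- c(msg, "degenerate geometry: filament width range must lie below the length range")
  if (object@breakProbability < 0 || object@breakProbability > 1)
    msg <- c(msg, "breakProbability must be in [0, 1]")
  if (object@styleFraction < 0 || object@styleFraction > 1)
    msg <- c(msg, "styleFraction must be in [0, 1]")
  if (length(object@stigmaColor) != 3L || any(object@stigmaColor < 0 | object@stigmaColor > 255))
    msg <- c(msg, "stigmaColor must be an RGB triple in 0..255")
  if (length(object@styleColor) != 3L || any(object@styleColor < 0 | object@styleColor > 255))
    msg <- c(msg, "styleColor must be an RGB triple in 0..255")
  if (object@backgroundLevel < 0L || object@backgroundLevel > 20L)
    msg <- c(msg, "backgroundLevel must be in 0..20")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@illuminationGradient < 0 || object@illuminationGradient > 1)
    msg <- c(msg, "illuminationGradient must be in [0, 1]")
  if (object@width < 256L || object@height < 256L)
    msg <- c(msg, "canvas must be at least 256 x 256")
  if (length(msg)) msg else TRUE
})

#' Glcm: a normalized gray-level co-occurrence matrix
#'
#' Joint probability \eqn{p(i, j)} that a pixel of quantized gray level
#' \eqn{i} co-occurs with a pixel of level \eqn{j} at a fixed spatial offset.
#' The matrix is symmetrized (each pair counted in both directions) and
#' normalized to sum to one.
#'
#' @slot p L x L numeric matrix of co-occurrence probabilities.
#' @slot levels number of quantized gray levels L.
#' @slot distance,angle the pixel offset: distance in pixels and angle in
#'   degrees (0, 45, 90 or 135 under the default registry).
#' @seealso [glcm()], [glcmStats()]
#' @export
setClass("Glcm", representation(
  p = "matrix", levels = "integer", distance = "integer", angle = "numeric"
))

setValidity("Glcm", function(object) {
  msg <- character()
  if (nrow(object@p) != object@levels || ncol(object@p) != object@levels)
    msg <- c(msg, "p must be levels x levels")
  if (any(object@p < 0)) msg <- c(msg, "p must be nonnegative")
  if (abs(sum(object@p) - 1) > 1e-9) msg <- c(msg, "p must sum to 1")
  if (length(msg)) msg else TRUE
})

#' CvResult: repeated cross-validation result for one classifier
#'
#' Holds the per-repetition pooled out-of-fold accuracies (percent scale) of
#' one classifier under repeated stratified k-fold cross-validation, together
#' with the pooled out-of-fold predicted labels and class-membership scores
#' of every repetition.
#'
#' @slot modelId,modelName identifier and display name of the classifier.
#' @slot accuracies numeric vector, one pooled accuracy (%) per repetition.
#' @slot predictions list (one per repetition) of factors of out-of-fold
#'   predicted labels, aligned with \code{labels}.
#' @slot scores list (one per repetition) of n x C numeric matrices of
#'   class-membership scores.
#' @slot labels factor of true labels.
#' @slot failures character vector describing any fold-level fit failures.
#' @seealso [runCV()], [meanAccuracy()], [sdAccuracy()]
#' @export
setClass("CvResult", representation(
  modelId = "character", modelName = "character",
  accuracies = "numeric", predictions = "list", scores = "list",
  labels = "factor", failures = "character"
))

setValidity("CvResult", function(object) {
  msg <- character()
  if (any(object@accuracies < 0 | object@accuracies > 100, na.rm = TRUE))
    msg <- c(msg, "accuracies must be percentages in [0, 100]")
  if (length(object@predictions) != length(object@accuracies))
    msg <- c(msg, "one prediction set per repetition required")
  if (length(msg)) msg else TRUE
})

#' DuncanResult: homogeneous subsets from Duncan's multiple range test
#'
#' Result of Duncan's stepwise multiple range procedure applied to a set of
#' group means (here: per-repetition classifier accuracies). Groups sharing a
#' letter are not significantly different at the protection level
#' \eqn{1 - (1 - \alpha)^{r - 1}}.
#'
#' @slot means named numeric vector of group means, sorted decreasing.
#' @slot letters character vector aligned with \code{means}; one or more
#'   letters per group.
#' @slot alpha nominal significance level of a two-mean comparison.
#' @slot errorMeanSquare,dfWithin error mean square and residual degrees of
#'   freedom from the one-way ANOVA.
#' @slot nPerGroup common group size (the design is balanced).
#' @seealso [duncanGroups()], [anovaOneway()]
#' @export
setClass("DuncanResult", representation(
  means = "numeric", letters = "character", alpha = "numeric",
  errorMeanSquare = "numeric", dfWithin = "numeric", nPerGroup = "integer"
))

#' ModelSpec: one classifier preset
#'
#' A named, frozen hyperparameter preset for one member of the 22-classifier
#' suite. Family is one of \code{tree}, \code{discriminant}, \code{svm},
#' \code{knn}, \code{ensemble} (plus \code{baseline} for the dummy majority
#' model used in sanity checks, which is not part of the suite).
#'
#' @slot id machine-readable unique identifier.
#' @slot name display name (e.g. \code{"Quadratic SVM"}).
#' @slot family model family.
#' @slot params list of hyperparameters for the family's fitting routine.
#' @seealso [modelSuite()], [runCV()]
#' @export
setClass("ModelSpec", representation(
  id = "character", name = "character", family = "character", params = "list"
))

setValidity("ModelSpec", function(object) {
  fam <- c("tree", "discriminant", "svm", "knn", "ensemble", "baseline")
  if (!object@family %in% fam)
    sprintf("family must be one of %s", paste(fam, collapse = ", "))
  else TRUE
})
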