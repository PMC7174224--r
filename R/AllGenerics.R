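#' Accessors for package classes
#'
#' \code{glcmMatrix} returns the probability matrix of a [Glcm];
#' \code{meanAccuracy} and \code{sdAccuracy} summarize the per-repetition
#' accuracies of a [CvResult]; \code{accuracies} returns the raw
#' per-repetition vector; \code{groupLetters} returns the letter display of a
#' [DuncanResult] as a named character vector.
#'
#' @param object a package object.
#' @return See details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("glcmMatrix", function(object) standardGeneric("glcmMatrix"))

#' @rdname accessors
#' @export
setMethod("glcmMatrix", "Glcm", function(object) object@p)

#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(object) standardGeneric("meanAccuracy"))

#' @rdname accessors
#' @export
setMethod("meanAccuracy", "CvResult",
          function(object) mean(object@accuracies, na.rm = TRUE))

#' @rdname accessors
#' @export
setGeneric("sdAccuracy", function(object) standardGeneric("sdAccuracy"))

#' @rdname accessors
#' @export
setMethod("sdAccuracy", "CvResult",
          function(object) stats::sd(object@accuracies, na.rm = TRUE))

#' @rdname accessors
#' @export
setGeneric("accuracies", function(object) standardGeneric("accuracies"))

#' @rdname accessors
#' @export
setMethod("accuracies", "CvResult", function(object) object@accuracies)

#' @rdname accessors
#' @export
setGeneric("groupLetters", function(object) standardGeneric("groupLetters"))

#' @rdname accessors
#' @export
setMethod("groupLetters", "DuncanResult",
          function(object) setNames(object@letters, names(object@means)))

setMethod("show", "Glcm", function(object) {
  cat(sprintf("Glcm: %d levels, distance %d, angle %g deg\n",
              object@levels, object@distance, object@angle))
  s <- glcmStats(object)
  cat(sprintf("  contrast %.4f | correlation %.4f | energy %.4f | homogeneity %.4f\n",
              s["contrast"], s["correlation"], s["energy"], s["homogeneity"]))
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf("SceneParams: %s scene, %d filaments on %dx%d canvas (seed %d)\n",
              object@classLabel, object@nFilaments, object@width, object@height,
              object@seed))
  cat(sprintf("  length %g-%g px, width %g-%g px, break prob %.2f, triplets %s\n",
              object@filamentLength[1], object@filamentLength[2],
              object@filamentWidth[1], object@filamentWidth[2],
              object@breakProbability, object@tripletJoin))
  cat(sprintf("  target style fraction %.2f, background %d, noise sd %.1f\n",
              object@styleFraction, object@backgroundLevel, object@noiseSd))
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult: %s (%s)\n", object@modelName, object@modelId))
  cat(sprintf("  %d repetitions, accuracy %.2f%% (SD %.2f%%)\n",
              length(object@accuracies), meanAccuracy(object), sdAccuracy(object)))
  if (length(object@failures))
    cat(sprintf("  %d fold failures recorded\n", length(object@failures)))
})

setMethod("show", "DuncanResult", function(object) {
  cat(sprintf("Duncan's multiple range test (alpha = %.3f, EMS = %.4g, df = %g)\n",
              object@alpha, object@errorMeanSquare, object@dfWithin))
  df <- data.frame(mean = round(object@means, 3), group = object@letters)
  print(df)
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s [%s, family %s]\n",
              object@name, object@id, object@family))
})
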