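#' Accessors for feature and model containers
#'
#' \code{keypoints} and \code{descriptors} return the keypoint table and the
#' descriptor matrix of a \code{\linkS4class{SiftFeatures}} object;
#' \code{centroids} and \code{codebookSize} the centroid matrix and size of a
#' \code{\linkS4class{Codebook}}; \code{confusionMatrix},
#' \code{perClassMetrics} and \code{weightedMetrics} the parts of an
#' \code{\linkS4class{EvaluationReport}}.
#'
#' @param x the object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("keypoints", function(x) standardGeneric("keypoints"))

#' @rdname accessors
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("codebookSize", function(x) standardGeneric("codebookSize"))

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname accessors
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname accessors
#' @export
setGeneric("weightedMetrics", function(x) standardGeneric("weightedMetrics"))

#' @rdname accessors
#' @export
setMethod("keypoints", "SiftFeatures", function(x) x@keypoints)

#' @rdname accessors
#' @export
setMethod("descriptors", "SiftFeatures", function(x) x@descriptors)

#' @rdname accessors
#' @export
setMethod("length", "SiftFeatures", function(x) nrow(x@keypoints))

#' @rdname accessors
#' @export
setMethod("centroids", "Codebook", function(x) x@centroids)

#' @rdname accessors
#' @export
setMethod("codebookSize", "Codebook", function(x) nrow(x@centroids))

#' @rdname accessors
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(x) x@confusion)

#' @rdname accessors
#' @export
setMethod("perClassMetrics", "EvaluationReport", function(x) x@perClass)

#' @rdname accessors
#' @export
setMethod("weightedMetrics", "EvaluationReport", function(x) x@weighted)

setMethod("show", "SiftParams", function(object) {
  cat(sprintf(
    "SiftParams: sigma0=%.3g CC=%.3g CE=%.3g intervals=%d octaves=%s%s\n",
    object@sigma0, object@contrastThreshold, object@edgeThreshold,
    object@intervals,
    if (is.na(object@nOctaves)) "auto" else as.character(object@nOctaves),
    if (object@upsample) " (pre-doubled)" else ""))
})

setMethod("show", "ScaleSpace", function(object) {
  cat(sprintf("ScaleSpace: %d octave(s) of %d images, input %dx%d\n",
              length(object@octaves), object@params@intervals + 3L,
              object@dim[1], object@dim[2]))
})

setMethod("show", "DogPyramid", function(object) {
  cat(sprintf("DogPyramid: %d octave(s) of %d difference images\n",
              length(object@octaves), object@params@intervals + 2L))
})

setMethod("show", "SiftFeatures", function(object) {
  cat(sprintf("SiftFeatures: %d keypoint(s) on a %dx%d image\n",
              nrow(object@keypoints), object@dim[1], object@dim[2]))
  if (nrow(object@keypoints) > 0) {
    cat(sprintf("  sigma range [%.2f, %.2f]\n",
                min(object@keypoints$sigma), max(object@keypoints$sigma)))
  }
})

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: %d codewords of dimension 128 (seed %d, WCSS %.4g)\n",
              nrow(object@centroids), object@seed, object@inertia))
})

setMethod("show", "KernelSpec", function(object) {
  if (object@kind == "rbf")
    cat(sprintf("KernelSpec: rbf (gamma=%.4g, C=%.4g)\n", object@gamma,
                object@cost))
  else cat(sprintf("KernelSpec: histogram intersection (C=%.4g)\n", object@cost))
})

setMethod("show", "HistoSvmModel", function(object) {
  cat(sprintf(
    "HistoSvmModel: %d classes (%s), %d one-vs-one machines, %d train rows\n",
    length(object@labels), paste(object@labels, collapse = ", "),
    length(object@machines), nrow(object@trainHistograms)))
  show(object@kernel)
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  print(object@confusion)
  pc <- object@perClass
  pc[, c("precision", "recall", "f")] <-
    round(pc[, c("precision", "recall", "f")], 4)
  print(pc, row.names = FALSE)
  w <- object@weighted
  cat(sprintf(
    "weighted: precision %.4f  recall %.4f  F %.4f  accuracy %.4f\n",
    w["precision"], w["recall"], w["f"], w["accuracy"]))
})

setMethod("show", "ClassSpec", function(object) {
  cat(sprintf(
    "ClassSpec '%s': radius %.1f+/-%.1f px, density %.1f/1e4px^2, ecc %.2f, contrast %.2f, jitter [%.2f, %.2f]\n",
    object@name, object@radiusMean, object@radiusSd, object@density,
    object@eccentricity, object@contrast, object@jitterRange[1],
    object@jitterRange[2]))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d images, %d classes, %d patients, %d sections (seed %d)\n",
    length(object@images), length(unique(object@labels)),
    length(unique(object@patient)), length(unique(object@section)),
    object@seed))
})
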