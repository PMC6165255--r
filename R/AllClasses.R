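#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict
#' @importFrom png readPNG writePNG
#' @importFrom tiff readTIFF
#' @importFrom jpeg readJPEG
#' @importFrom jsonlite toJSON fromJSON
#' @importFrom kernlab ksvm alphaindex b as.kernelMatrix
#' @useDynLib histosift, .registration = TRUE
NULL

#' Parameters of the scale-invariant feature detector
#'
#' Holds the free parameters of the keypoint detector: the base Gaussian
#' width \code{sigma0} of the scale-space schedule, the contrast threshold
#' \code{contrastThreshold} below which low-contrast keypoints are rejected,
#' the edge threshold \code{edgeThreshold} bounding the allowed ratio of
#' principal curvatures, the number of octaves (\code{NA} selects
#' \code{floor(log2(min(h, w))) - 2} automatically), the number of sampled
#' intervals per octave \code{s} (each octave then carries \code{s + 3}
#' smoothed images and adjacent scales differ by \code{k = 2^(1/s)}), and a
#' flag to pre-double the first octave.
#'
#' Defaults are the operating point selected on held-out histology tiles:
#' \code{sigma0 = 1.7}, \code{contrastThreshold = 0.04},
#' \code{edgeThreshold = 11}.
#'
#' @slot sigma0 base Gaussian width of the schedule (pixels).
#' @slot contrastThreshold minimum absolute interpolated DoG response.
#' @slot edgeThreshold maximum principal-curvature ratio.
#' @slot nOctaves integer number of octaves, or \code{NA} for automatic.
#' @slot intervals sampled intervals per octave.
#' @slot upsample pre-double the input before the first octave.
#' @export
setClass("SiftParams",
  representation(sigma0 = "numeric", contrastThreshold = "numeric",
                 edgeThreshold = "numeric", nOctaves = "integer",
                 intervals = "integer", upsample = "logical"),
  prototype(sigma0 = 1.7, contrastThreshold = 0.04, edgeThreshold = 11,
            nOctaves = NA_integer_, intervals = 3L, upsample = FALSE),
  validity = function(object) {
    msg <- character()
    if (length(object@sigma0) != 1 || !is.finite(object@sigma0) ||
        object@sigma0 <= 0)
      msg <- c(msg, "sigma0 must be a single positive number")
    if (length(object@contrastThreshold) != 1 ||
        !is.finite(object@contrastThreshold) || object@contrastThreshold <= 0)
      msg <- c(msg, "contrastThreshold must be a single positive number")
    if (length(object@edgeThreshold) != 1 ||
        !is.finite(object@edgeThreshold) || object@edgeThreshold < 1)
      msg <- c(msg, "edgeThreshold must be >= 1")
    if (length(object@nOctaves) != 1 ||
        (!is.na(object@nOctaves) && object@nOctaves < 1))
      msg <- c(msg, "nOctaves must be NA or a positive integer")
    if (length(object@intervals) != 1 || is.na(object@intervals) ||
        object@intervals < 1)
      msg <- c(msg, "intervals must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' @rdname SiftParams-class
#' @param sigma0,contrastThreshold,edgeThreshold,nOctaves,intervals,upsample
#'   see the class slots.
#' @return a validated \code{SiftParams} object.
#' @examples
#' siftParams()                     # histology defaults
#' siftParams(sigma0 = 1.6, upsample = TRUE)
#' @export
siftParams <- function(sigma0 = 1.7, contrastThreshold = 0.04,
                       edgeThreshold = 11, nOctaves = NA, intervals = 3L,
                       upsample = FALSE) {
  new("SiftParams", sigma0 = as.numeric(sigma0),
      contrastThreshold = as.numeric(contrastThreshold),
      edgeThreshold = as.numeric(edgeThreshold),
      nOctaves = as.integer(nOctaves), intervals = as.integer(intervals),
      upsample = isTRUE(upsample))
}

#' Gaussian scale space of an image
#'
#' An ordered set of octaves; each octave holds \code{s + 3} progressively
#' smoothed images \code{L(x, y, sigma)} whose scales grow by the factor
#' \code{k = 2^(1/s)}, plus the mapping from octave pixel coordinates back to
#' the full-resolution frame.
#'
#' @slot octaves list; each element has \code{images} (list of matrices),
#'   \code{sigmas} (absolute scales in input-image units, strictly
#'   increasing), \code{octSigmas} (scales in octave pixel units) and
#'   \code{factor} (octave pixel size relative to the input image).
#' @slot params the \code{SiftParams} used to build it.
#' @slot dim height and width of the input image.
#' @export
setClass("ScaleSpace",
  representation(octaves = "list", params = "SiftParams", dim = "integer"),
  validity = function(object) {
    s <- object@params@intervals
    for (o in object@octaves) {
      if (length(o$images) != s + 3)
        return(sprintf("each octave must hold s + 3 = %d images", s + 3))
      if (any(diff(o$sigmas) <= 0))
        return("sigma values must be strictly increasing within an octave")
    }
    if (length(object@octaves) >= 2) {
      d1 <- dim(object@octaves[[1]]$images[[1]])
      d2 <- dim(object@octaves[[2]]$images[[1]])
      if (any(d2 != ((d1 + 1L) %/% 2L)))
        return("spatial size must halve between consecutive octaves")
    }
    TRUE
  })

#' Difference-of-Gaussians pyramid
#'
#' Per octave, the \code{s + 2} elementwise differences of adjacent smoothed
#' images of a \code{ScaleSpace}; scale-space extrema of these difference
#' images are the keypoint candidates.
#'
#' @slot octaves list mirroring \code{ScaleSpace}: \code{images} (s + 2
#'   difference matrices), \code{sigmas} (absolute scale of the lower image
#'   of each pair), \code{octSigmas}, \code{factor}.
#' @slot params the originating \code{SiftParams}.
#' @slot dim input image dimensions.
#' @export
setClass("DogPyramid",
  representation(octaves = "list", params = "SiftParams", dim = "integer"),
  validity = function(object) {
    s <- object@params@intervals
    for (o in object@octaves)
      if (length(o$images) != s + 2)
        return(sprintf("each octave must hold s + 2 = %d difference images",
                       s + 2))
    TRUE
  })

#' Keypoints with their descriptors
#'
#' The result of feature extraction on one image: a table of localized,
#' scale-assigned, oriented keypoints and the matching 128-element
#' gradient-orientation descriptors (one row each).
#'
#' @slot keypoints data.frame with columns \code{x}, \code{y} (sub-pixel,
#'   full-resolution frame, 0-based), \code{octave}, \code{interval},
#'   \code{sigma} (absolute scale), \code{orientation} (degrees in
#'   [0, 360)), \code{response} (interpolated DoG value).
#' @slot descriptors numeric matrix, one 128-element row per keypoint.
#' @slot dim height and width of the source image.
#' @export
setClass("SiftFeatures",
  representation(keypoints = "data.frame", descriptors = "matrix",
                 dim = "integer"),
  validity = function(object) {
    need <- c("x", "y", "octave", "interval", "sigma", "orientation",
              "response")
    if (!all(need %in% names(object@keypoints)))
      return(paste("keypoints must have columns", paste(need, collapse = ", ")))
    if (nrow(object@keypoints) != nrow(object@descriptors))
      return("keypoints and descriptors must have matching row counts")
    if (nrow(object@descriptors) > 0 && ncol(object@descriptors) != 128)
      return("descriptors must have exactly 128 columns")
    kp <- object@keypoints
    if (nrow(kp) > 0) {
      if (any(kp$sigma <= 0)) return("keypoint sigma must be positive")
      if (any(kp$orientation < 0 | kp$orientation >= 360))
        return("orientation must lie in [0, 360)")
    }
    TRUE
  })

#' Codeword codebook
#'
#' \code{k} cluster centroids in 128-dimensional descriptor space, fitted by
#' k-means over training descriptors; the quantization targets
#' ("codewords") of the bag-of-features encoding.
#'
#' @slot centroids k x 128 numeric matrix.
#' @slot seed integer seed used for the clustering initialization.
#' @slot inertia within-cluster sum of squares of the retained fit.
#' @export
setClass("Codebook",
  representation(centroids = "matrix", seed = "integer", inertia = "numeric"),
  validity = function(object) {
    if (nrow(object@centroids) < 2) return("a codebook needs k >= 2 centroids")
    if (ncol(object@centroids) != 128)
      return("centroids must have 128 components")
    if (!all(is.finite(object@centroids)))
      return("all centroid components must be finite")
    if (anyDuplicated(object@centroids)) return("duplicate centroids")
    TRUE
  })

#' Kernel specification for the histogram classifier
#'
#' @slot kind \code{"rbf"} (Gaussian radial basis,
#'   \code{K(a,b) = exp(-gamma * ||a - b||^2)}) or
#'   \code{"histogram_intersection"} (\code{K(a,b) = sum(pmin(a, b))}).
#' @slot gamma RBF width; default 0.004, the value selected empirically on
#'   held-out histology tiles.
#' @slot C soft-margin penalty of the SVM.
#' @export
setClass("KernelSpec",
  representation(kind = "character", gamma = "numeric", cost = "numeric"),
  prototype(kind = "rbf", gamma = 0.004, cost = 1.0),
  validity = function(object) {
    if (!object@kind %in% c("rbf", "histogram_intersection"))
      return("kind must be 'rbf' or 'histogram_intersection'")
    if (object@kind == "rbf" &&
        (!is.finite(object@gamma) || object@gamma <= 0))
      return("gamma must be positive for the rbf kernel")
    if (!is.finite(object@cost) || object@cost <= 0) return("C must be positive")
    TRUE
  })

#' @rdname KernelSpec-class
#' @param kind,gamma,C see the class slots.
#' @export
kernelSpec <- function(kind = c("rbf", "histogram_intersection"),
                       gamma = 0.004, C = 1.0) {
  kind <- match.arg(kind)
  new("KernelSpec", kind = kind, gamma = as.numeric(gamma), cost = as.numeric(C))
}

#' Trained one-vs-one SVM over bag-of-features histograms
#'
#' Stores, per class pair, the support-vector coefficients, offset and sign
#' convention of a soft-margin SVM trained on a precomputed Gram matrix,
#' together with the training histograms needed to evaluate kernel rows at
#' prediction time and a fingerprint of the codebook in effect at training.
#'
#' @slot kernel the \code{KernelSpec}.
#' @slot labels ordered class labels seen in training.
#' @slot machines list of per-pair fits (indices, coefficients, offset,
#'   positive/negative label assignment).
#' @slot trainHistograms training histograms (rows).
#' @slot codebookHash fingerprint of the codebook used at train time.
#' @export
setClass("HistoSvmModel",
  representation(kernel = "KernelSpec", labels = "character",
                 machines = "list", trainHistograms = "matrix",
                 codebookHash = "character"),
  validity = function(object) {
    if (length(object@labels) < 2) return("at least two classes required")
    if (length(object@machines) !=
        choose(length(object@labels), 2))
      return("one machine per unordered class pair is required")
    TRUE
  })

#' Classification evaluation report
#'
#' Confusion matrix (rows = actual, columns = predicted) with per-class and
#' support-weighted precision, recall and F-measure.
#'
#' @slot confusion square integer matrix with class dimnames.
#' @slot perClass data.frame: class, support, precision, recall, f.
#' @slot weighted named numeric: precision, recall, f, accuracy.
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 weighted = "numeric"),
  validity = function(object) {
    if (nrow(object@confusion) != ncol(object@confusion))
      return("confusion matrix must be square")
    if (any(object@confusion < 0)) return("confusion counts must be >= 0")
    w <- object@weighted
    if (!all(c("precision", "recall", "f", "accuracy") %in% names(w)))
      return("weighted must name precision, recall, f, accuracy")
    if (any(w < -1e-12 | w > 1 + 1e-12))
      return("weighted metrics must lie in [0, 1]")
    TRUE
  })

#' Synthetic texture class specification
#'
#' Parameters of one class of histology-like synthetic texture: blob-shaped
#' "cells" whose radius distribution, packing density, eccentricity and
#' contrast characterize the class, with a per-image global scale jitter
#' emulating the large within-class variation of cell size seen in
#' neuroblastic tumour tiles.
#'
#' @slot name class label.
#' @slot radiusMean,radiusSd Gaussian-blob radius distribution (pixels).
#' @slot density expected cells per 1e4 px^2.
#' @slot eccentricity blob eccentricity in [0, 1).
#' @slot contrast blob amplitude against the background, in (0, 1].
#' @slot noiseSd additive background noise standard deviation.
#' @slot jitterRange per-image global scale factor range.
#' @export
setClass("ClassSpec",
  representation(name = "character", radiusMean = "numeric",
                 radiusSd = "numeric", density = "numeric",
                 eccentricity = "numeric", contrast = "numeric",
                 noiseSd = "numeric", jitterRange = "numeric"),
  validity = function(object) {
    if (object@radiusMean <= 1) return("radiusMean must exceed 1 pixel")
    if (object@density <= 0) return("density must be positive")
    if (object@eccentricity < 0 || object@eccentricity >= 1)
      return("eccentricity must lie in [0, 1)")
    if (object@contrast <= 0 || object@contrast > 1)
      return("contrast must lie in (0, 1]")
    if (length(object@jitterRange) != 2 ||
        any(object@jitterRange <= 0) || diff(object@jitterRange) < 0)
      return("jitterRange must be an increasing pair of positive factors")
    vals <- c(object@radiusMean, object@radiusSd, object@density,
              object@noiseSd, object@jitterRange)
    if (!all(is.finite(vals))) return("all parameters must be finite")
    TRUE
  })

#' @rdname ClassSpec-class
#' @param name,radiusMean,radiusSd,density,eccentricity,contrast,noiseSd,jitterRange
#'   see the class slots.
#' @export
classSpec <- function(name, radiusMean, radiusSd = radiusMean / 4, density = 5,
                      eccentricity = 0, contrast = 0.8, noiseSd = 0.02,
                      jitterRange = c(0.7, 1.4)) {
  new("ClassSpec", name = as.character(name),
      radiusMean = as.numeric(radiusMean), radiusSd = as.numeric(radiusSd),
      density = as.numeric(density), eccentricity = as.numeric(eccentricity),
      contrast = as.numeric(contrast), noiseSd = as.numeric(noiseSd),
      jitterRange = as.numeric(jitterRange))
}

#' Seeded synthetic dataset
#'
#' A balanced, labelled collection of synthetic texture tiles grouped into
#' pseudo-patients and pseudo-sections so that patient-level recognition
#' rates and section-level majority votes can be exercised end to end.
#'
#' @slot images list of grayscale matrices (values in [0, 1]).
#' @slot labels class label per image.
#' @slot patient pseudo-patient id per image.
#' @slot section pseudo-section id per image.
#' @slot seed the master seed.
#' @slot specs the generating \code{ClassSpec} list.
#' @export
setClass("SyntheticDataset",
  representation(images = "list", labels = "character", patient = "character",
                 section = "character", seed = "integer", specs = "list"),
  validity = function(object) {
    n <- length(object@images)
    if (length(object@labels) != n || length(object@patient) != n ||
        length(object@section) != n)
      return("images, labels, patient and section must have equal length")
    specNames <- vapply(object@specs, function(s) s@name, character(1))
    if (!setequal(unique(object@labels), specNames))
      return("label set must equal the spec names")
    TRUE
  })
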