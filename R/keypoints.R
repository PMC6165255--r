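#' Detect candidate keypoints as 26-neighbor extrema
#'
#' Scans every interior sample of the difference-of-Gaussians pyramid and
#' keeps those strictly greater than all 26 neighbors or strictly less than
#' all 26 (8 in the same difference image, 9 in the scale above, 9 below).
#' Only interior intervals and pixels at least one sample from the spatial
#' border are eligible.
#'
#' @param dog a \code{\linkS4class{DogPyramid}}.
#' @return data.frame of candidates with 0-based octave-grid coordinates
#'   \code{row}, \code{col}, \code{interval} and the 1-based \code{octave}.
#'   Zero rows when the image has no strict extrema (e.g. a constant image).
#' @export
detectExtrema <- function(dog) {
  stopifnot(is(dog, "DogPyramid"))
  out <- lapply(seq_along(dog@octaves), function(o) {
    m <- cpp_detect_extrema(dog@octaves[[o]]$images)
    data.frame(octave = rep.int(o, nrow(m)), row = m[, 1], col = m[, 2],
               interval = m[, 3])
  })
  do.call(rbind, out)
}

#' Localize keypoints to sub-pixel accuracy and reject unstable ones
#'
#' Fits a 3D quadratic to the DoG around each candidate and solves
#' \code{z = -(d2D/dx2)^-1 (dD/dx)} over (x, y, scale) by finite
#' differences, re-centering while any offset component exceeds 0.5 (up to
#' \code{maxIter} passes).  Candidates whose interpolated response falls
#' below the contrast threshold, whose quadratic is singular, or whose
#' refinement leaves the valid domain are rejected.
#'
#' @param dog a \code{\linkS4class{DogPyramid}}.
#' @param candidates output of \code{\link{detectExtrema}} (default: computed
#'   here).
#' @param params \code{\link{siftParams}}; supplies the contrast threshold,
#'   applied to the interpolated response of images scaled to [0, 1].
#' @param maxIter re-centering cap.
#' @return data.frame of localized keypoints: full-resolution sub-pixel
#'   \code{x}, \code{y}; \code{octave}; refined fractional \code{interval};
#'   integer octave-grid \code{row}, \code{col}, \code{intLevel} of the final
#'   fit; absolute \code{sigma}; interpolated \code{response}; and
#'   \code{status} (\code{0} kept, \code{1} low contrast, \code{2} singular
#'   fit, \code{3} out of bounds).  Rows with \code{status != 0} are the
#'   rejected candidates.
#' @export
localizeKeypoints <- function(dog, candidates = detectExtrema(dog),
                              params = dog@params, maxIter = 5L) {
  stopifnot(is(dog, "DogPyramid"))
  if (is.null(candidates) || nrow(candidates) == 0) return(.emptyLocalized())
  out <- lapply(split(candidates, candidates$octave), function(cand) {
    o <- cand$octave[1]
    oct <- dog@octaves[[o]]
    res <- cpp_localize(oct$images,
                        as.matrix(cand[, c("row", "col", "interval")]),
                        params@contrastThreshold, as.integer(maxIter))
    s <- dog@params@intervals
    data.frame(
      x = res[, "col"] * oct$factor,
      y = res[, "row"] * oct$factor,
      octave = rep.int(o, nrow(res)),
      interval = res[, "interval"],
      row = as.integer(round(res[, "row"])),
      col = as.integer(round(res[, "col"])),
      intLevel = pmin(pmax(as.integer(round(res[, "interval"])), 1L), s),
      sigma = params@sigma0 * 2^(res[, "interval"] / s) * oct$factor,
      response = res[, "response"],
      status = as.integer(res[, "status"]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.emptyLocalized <- function() {
  data.frame(x = numeric(), y = numeric(), octave = integer(),
             interval = numeric(), row = integer(), col = integer(),
             intLevel = integer(), sigma = numeric(), response = numeric(),
             status = integer())
}

#' Reject keypoints with edge-like curvature
#'
#' Computes the 2x2 spatial Hessian of the DoG at each keypoint by finite
#' differences and discards keypoints whose principal-curvature ratio
#' exceeds the edge threshold, via the ratio test
#' \code{Tr(H)^2 / Det(H) >= (CE + 1)^2 / CE} (discarded at equality, and
#' whenever \code{Det(H) <= 0}).
#'
#' @param dog a \code{\linkS4class{DogPyramid}}.
#' @param kps localized keypoints from \code{\link{localizeKeypoints}}.
#' @param edgeThreshold the curvature-ratio bound CE.
#' @return logical vector: \code{TRUE} for keypoints to keep.
#' @export
rejectEdgeResponse <- function(dog, kps,
                               edgeThreshold = dog@params@edgeThreshold) {
  stopifnot(is(dog, "DogPyramid"))
  if (nrow(kps) == 0) return(logical(0))
  keep <- logical(nrow(kps))
  for (o in unique(kps$octave)) {
    idx <- which(kps$octave == o)
    oct <- dog@octaves[[o]]
    d <- dim(oct$images[[1]])
    r <- pmin(pmax(kps$row[idx], 1L), d[1] - 2L)
    c <- pmin(pmax(kps$col[idx], 1L), d[2] - 2L)
    pts <- cbind(r, c, kps$intLevel[idx])
    keep[idx] <- cpp_edge_keep(oct$images, pts, edgeThreshold)
  }
  keep
}

#' Assign dominant orientations to keypoints
#'
#' Builds a 36-bin histogram of local gradient orientations around each
#' keypoint in the smoothed image closest to its scale; each sample is
#' weighted by its gradient magnitude \code{m(x, y)} and by a circular
#' Gaussian of width 1.5 times the keypoint scale.  Every histogram peak
#' reaching at least 80% of the maximum emits one oriented keypoint (so a
#' keypoint can appear several times with the same location and scale but
#' different directions), with the peak position refined by parabolic
#' interpolation over its two neighbors.
#'
#' @param ss the \code{\linkS4class{ScaleSpace}} the pyramid came from.
#' @param kps localized keypoints that survived both rejection tests.
#' @return the keypoint data.frame, expanded to one row per emitted
#'   orientation, with an \code{orientation} column in degrees [0, 360).
#'   An all-zero gradient region emits orientation 0 with a warning.
#' @export
assignOrientations <- function(ss, kps) {
  stopifnot(is(ss, "ScaleSpace"))
  if (nrow(kps) == 0) return(cbind(kps, orientation = numeric(0)))
  rows <- vector("list", nrow(kps))
  flat <- FALSE
  for (i in seq_len(nrow(kps))) {
    oct <- ss@octaves[[kps$octave[i]]]
    lev <- min(max(as.integer(round(kps$interval[i])) + 1L, 1L),
               length(oct$images))
    octSigma <- ss@params@sigma0 * 2^(kps$interval[i] / ss@params@intervals)
    h <- cpp_orientation_hist(oct$images[[lev]],
                              kps$x[i] / oct$factor, kps$y[i] / oct$factor,
                              octSigma)
    oris <- .histogramPeaks(h)
    if (is.null(oris)) {
      flat <- TRUE
      oris <- 0
    }
    rw <- kps[rep.int(i, length(oris)), , drop = FALSE]
    rw$orientation <- oris
    rows[[i]] <- rw
  }
  if (flat)
    warning("keypoint(s) with an all-zero gradient region: orientation 0 assigned")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Peaks >= 80% of the maximum of a circular 36-bin histogram, refined by a
# parabola through the peak and its two neighbors.  The histogram is first
# smoothed with a circular [1, 4, 6, 4, 1]/16 kernel (twice) to stabilize
# peaks against sampling-grid shifts.  NULL for an empty histogram.
.histogramPeaks <- function(h, nbins = 36L, peakFrac = 0.8) {
  if (max(h) <= 0) return(NULL)
  for (pass in 1:2) {
    h <- (h[c(nbins - 1L, nbins, seq_len(nbins - 2L))] +
          4 * h[c(nbins, seq_len(nbins - 1L))] + 6 * h +
          4 * h[c(2:nbins, 1L)] +
          h[c(3:nbins, 1L, 2L)]) / 16
  }
  mx <- max(h)
  left <- h[c(nbins, seq_len(nbins - 1L))]
  right <- h[c(2:nbins, 1L)]
  peaks <- which(h > left & h > right & h >= peakFrac * mx)
  if (length(peaks) == 0) peaks <- which.max(h)
  vapply(peaks, function(b) {
    l <- left[b]; r <- right[b]; cc <- h[b]
    denom <- l - 2 * cc + r
    off <- if (abs(denom) < 1e-12) 0 else 0.5 * (l - r) / denom
    ((b - 0.5 + off) * (360 / nbins)) %% 360
  }, numeric(1))
}

#' Compute 128-element descriptors for oriented keypoints
#'
#' Samples image gradients in a window of 4x4 sub-regions (each 3 sigma
#' wide) around the keypoint, rotated by minus its orientation for rotation
#' invariance, and accumulates them into 4 x 4 x 8 = 128 orientation-bin
#' counts with trilinear interpolation and a Gaussian spatial weight.
#' Samples falling outside the image contribute zero.  Each vector is
#' normalized to unit length, clamped at 0.2 to tame saturated gradients
#' (illumination robustness), and renormalized.
#'
#' @param ss the \code{\linkS4class{ScaleSpace}}.
#' @param kps oriented keypoints from \code{\link{assignOrientations}}.
#' @return list with \code{descriptors} (matrix, one 128-element row per
#'   keypoint) and \code{ok} (logical; \code{FALSE} flags zero-gradient
#'   windows whose descriptor cannot be normalized and must not be used).
#' @export
computeDescriptors <- function(ss, kps) {
  stopifnot(is(ss, "ScaleSpace"))
  n <- nrow(kps)
  desc <- matrix(0, n, 128L)
  ok <- rep.int(TRUE, n)
  for (i in seq_len(n)) {
    oct <- ss@octaves[[kps$octave[i]]]
    lev <- min(max(as.integer(round(kps$interval[i])) + 1L, 1L),
               length(oct$images))
    octSigma <- ss@params@sigma0 * 2^(kps$interval[i] / ss@params@intervals)
    v <- cpp_descriptor_raw(oct$images[[lev]],
                            kps$x[i] / oct$factor, kps$y[i] / oct$factor,
                            octSigma, kps$orientation[i])
    nrm <- sqrt(sum(v^2))
    if (nrm < 1e-12) {
      ok[i] <- FALSE
      next
    }
    v <- pmin(v / nrm, 0.2)
    desc[i, ] <- v / sqrt(sum(v^2))
  }
  list(descriptors = desc, ok = ok)
}

#' Extract scale-invariant features from an image
#'
#' Runs the full detector: scale-space construction, difference-of-Gaussians
#' extrema detection, sub-pixel localization with contrast rejection,
#' edge-response rejection, orientation assignment and descriptor
#' extraction.  Deterministic for fixed input and parameters.
#'
#' @param image numeric matrix in [0, 1].
#' @param params \code{\link{siftParams}}.
#' @return a \code{\linkS4class{SiftFeatures}} object; zero keypoints (e.g.
#'   on a blank image) gives an empty object, never an error.
#' @examples
#' img <- renderImage(classSpec("a", radiusMean = 4, density = 8), seed = 2,
#'                    dim = c(96, 96))
#' fts <- extractFeatures(img)
#' fts
#' @export
extractFeatures <- function(image, params = siftParams()) {
  ss <- buildScaleSpace(image, params)
  dog <- computeDog(ss)
  loc <- localizeKeypoints(dog, params = params)
  loc <- loc[loc$status == 0L, , drop = FALSE]
  if (nrow(loc) > 0)
    loc <- loc[rejectEdgeResponse(dog, loc), , drop = FALSE]
  if (nrow(loc) == 0) return(.emptyFeatures(dim(image)))
  oriented <- assignOrientations(ss, loc)
  dd <- computeDescriptors(ss, oriented)
  oriented <- oriented[dd$ok, , drop = FALSE]
  desc <- dd$descriptors[dd$ok, , drop = FALSE]
  # clip rare sub-pixel drift beyond the frame
  inb <- oriented$x >= 0 & oriented$x < ss@dim[2] &
         oriented$y >= 0 & oriented$y < ss@dim[1]
  oriented <- oriented[inb, , drop = FALSE]
  desc <- desc[inb, , drop = FALSE]
  kp <- oriented[, c("x", "y", "octave", "interval", "sigma", "orientation",
                     "response")]
  rownames(kp) <- NULL
  new("SiftFeatures", keypoints = kp, descriptors = desc, dim = dim(image))
}

.emptyFeatures <- function(d) {
  new("SiftFeatures",
      keypoints = data.frame(x = numeric(), y = numeric(),
                             octave = integer(), interval = numeric(),
                             sigma = numeric(), orientation = numeric(),
                             response = numeric()),
      descriptors = matrix(0, 0, 128L), dim = as.integer(d))
}

#' Write keypoints and descriptors to a sidecar file
#'
#' Tab-separated text with header line \code{#histosift-kp v1}: columns
#' \code{x}, \code{y}, \code{sigma}, \code{orientation_deg},
#' \code{response}, followed by the 128 descriptor values.
#'
#' @param features a \code{\linkS4class{SiftFeatures}} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeKeypoints <- function(features, path) {
  stopifnot(is(features, "SiftFeatures"))
  kp <- features@keypoints
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#histosift-kp v1", con)
  if (nrow(kp) > 0) {
    tab <- cbind(kp$x, kp$y, kp$sigma, kp$orientation, kp$response,
                 features@descriptors)
    utils::write.table(format(tab, digits = 9, trim = TRUE, scientific = NA),
                       con, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
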