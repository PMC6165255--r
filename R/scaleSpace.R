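#' Build the Gaussian scale space of an image
#'
#' Convolves the image with Gaussians of geometrically increasing width to
#' obtain \code{L(x, y, sigma)}.  Each octave holds \code{s + 3} images whose
#' scales grow by \code{k = 2^(1/s)}; smoothing is incremental, so the
#' cumulative blur of interval \code{i} equals \code{sigma0 * k^i}.  The next
#' octave starts from the image with twice the base scale, downsampled by
#' two.  The raw input is assumed to carry a nominal blur of 0.5 pixels
#' (1.0 after pre-doubling) and is first brought up to \code{sigma0}.
#'
#' @param image numeric matrix with intensities in [0, 1] (use
#'   \code{\link{loadImageAsGray}} for files).
#' @param params a \code{\link{siftParams}} object.
#' @return a \code{\linkS4class{ScaleSpace}}.
#' @examples
#' img <- renderImage(classSpec("a", radiusMean = 4), seed = 1,
#'                    dim = c(64, 64))
#' ss <- buildScaleSpace(img, siftParams(nOctaves = 3))
#' ss
#' @export
buildScaleSpace <- function(image, params = siftParams()) {
  .checkGray(image)
  validObject(params)
  s <- params@intervals
  k <- 2^(1 / s)

  base <- image
  baseBlur <- 0.5          # nominal blur of the raw input
  factor0 <- 1
  if (params@upsample) {
    base <- cpp_upsample2(base)
    baseBlur <- 1.0
    factor0 <- 0.5
  }
  # the deepest octave must keep at least 8 px so that the 26-neighbor cube
  # and the descriptor window remain meaningful
  maxOct <- max(1L, floor(log2(min(dim(base)))) - 2L)
  nOct <- params@nOctaves
  if (is.na(nOct)) nOct <- maxOct
  if (nOct > maxOct) {
    warning(sprintf(
      "image of size %dx%d supports only %d octave(s); reducing from %d",
      nrow(image), ncol(image), maxOct, nOct))
    nOct <- maxOct
  }

  if (params@sigma0 > baseBlur)
    base <- cpp_gauss_blur(base, sqrt(params@sigma0^2 - baseBlur^2))

  octSigmas <- params@sigma0 * k^(0:(s + 2))
  increments <- sqrt(diff(octSigmas^2))
  octaves <- vector("list", nOct)
  for (o in seq_len(nOct)) {
    images <- vector("list", s + 3)
    images[[1]] <- base
    for (i in 2:(s + 3))
      images[[i]] <- cpp_gauss_blur(images[[i - 1]], increments[i - 1])
    fac <- factor0 * 2^(o - 1)
    octaves[[o]] <- list(images = images, sigmas = octSigmas * fac,
                         octSigmas = octSigmas, factor = fac)
    if (o < nOct) base <- cpp_downsample(images[[s + 1]])  # sigma = 2*sigma0
  }
  new("ScaleSpace", octaves = octaves, params = params,
      dim = dim(image))
}

#' Difference-of-Gaussians pyramid
#'
#' Subtracts adjacent smoothed images of every octave,
#' \code{D_i = L_{i+1} - L_i}, giving \code{s + 2} difference images per
#' octave whose scale-space extrema are the keypoint candidates.
#'
#' @param ss a \code{\linkS4class{ScaleSpace}}.
#' @return a \code{\linkS4class{DogPyramid}}.
#' @export
computeDog <- function(ss) {
  stopifnot(is(ss, "ScaleSpace"))
  octaves <- lapply(ss@octaves, function(o) {
    n <- length(o$images)
    list(images = lapply(seq_len(n - 1),
                         function(i) o$images[[i + 1]] - o$images[[i]]),
         sigmas = o$sigmas[-n], octSigmas = o$octSigmas[-n],
         factor = o$factor)
  })
  new("DogPyramid", octaves = octaves, params = ss@params, dim = ss@dim)
}
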