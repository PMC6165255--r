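# Seeded generator of histology-like synthetic textures: Poisson-distributed
# elliptical Gaussian blobs ("cells") on a light background, with a per-image
# global scale jitter emulating the large within-class variation in cell size
# that motivates scale-invariant features.

#' Default five-class synthetic texture suite
#'
#' Five texture classes separable by local gradient statistics — cell size,
#' packing density, eccentricity and contrast all differ — while every class
#' carries deliberate within-class scale variation through the per-image
#' jitter factor.
#'
#' @param jitter logical; \code{FALSE} fixes the per-image scale factor at 1
#'   (the no-jitter control used to quantify scale robustness).
#' @return list of five \code{\linkS4class{ClassSpec}} objects.
#' @export
defaultClassSpecs <- function(jitter = TRUE) {
  jr <- if (jitter) c(0.7, 1.4) else c(1, 1)
  list(
    classSpec("small-dense", radiusMean = 3, radiusSd = 0.8, density = 14,
              eccentricity = 0.05, contrast = 0.95, noiseSd = 0,
              jitterRange = jr),
    classSpec("small-sparse", radiusMean = 3, radiusSd = 0.8, density = 4,
              eccentricity = 0.45, contrast = 0.90, noiseSd = 0.08,
              jitterRange = jr),
    classSpec("large-dense", radiusMean = 7, radiusSd = 1.8, density = 5,
              eccentricity = 0.85, contrast = 0.70, noiseSd = 0,
              jitterRange = jr),
    classSpec("large-sparse", radiusMean = 7, radiusSd = 1.8, density = 2,
              eccentricity = 0.05, contrast = 0.95, noiseSd = 0.03,
              jitterRange = jr),
    classSpec("mixed-size", radiusMean = 5, radiusSd = 3, density = 8,
              eccentricity = 0.60, contrast = 0.85, noiseSd = 0.02,
              jitterRange = jr))
}

#' Render one synthetic texture image
#'
#' Draws a Poisson number of cells (expectation \code{density} per 1e4 px^2),
#' places each uniformly with a Gaussian-distributed radius scaled by a
#' per-image global jitter factor drawn from the spec range, renders cells as
#' dark elliptical Gaussian blobs on a light background, adds Gaussian
#' background noise and clips to [0, 1].  Deterministic per (spec, seed).
#'
#' @param spec a \code{\linkS4class{ClassSpec}}.
#' @param seed integer seed.
#' @param dim height and width in pixels (default 300 x 300).
#' @return numeric matrix in [0, 1].
#' @export
renderImage <- function(spec, seed, dim = c(300L, 300L)) {
  validObject(spec)
  h <- as.integer(dim[1]); w <- as.integer(dim[2])
  maxR <- spec@radiusMean * max(spec@jitterRange)
  coverage <- spec@density / 1e4 * pi * maxR^2
  if (coverage > 0.5)
    stop(sprintf("degenerate texture: expected blob coverage %.0f%% > 50%%",
                 100 * coverage))
  .withSeed(seed, {
    img <- matrix(0.85, h, w)
    jitterF <- stats::runif(1, spec@jitterRange[1], spec@jitterRange[2])
    nCells <- stats::rpois(1, spec@density * h * w / 1e4)
    for (i in seq_len(nCells)) {
      cx <- stats::runif(1, 0, w - 1)
      cy <- stats::runif(1, 0, h - 1)
      r <- max(1, stats::rnorm(1, spec@radiusMean, spec@radiusSd)) * jitterF
      ang <- stats::runif(1, 0, pi)
      amp <- spec@contrast * stats::runif(1, 0.7, 1)
      minor <- r * sqrt(1 - spec@eccentricity^2)
      R <- ceiling(3 * r)
      rows <- max(1, floor(cy) - R + 1):min(h, ceiling(cy) + R + 1)
      cols <- max(1, floor(cx) - R + 1):min(w, ceiling(cx) + R + 1)
      dy <- (rows - 1) - cy
      dx <- (cols - 1) - cx
      u <- outer(dy, dx, function(yy, xx) xx * cos(ang) + yy * sin(ang))
      v <- outer(dy, dx, function(yy, xx) -xx * sin(ang) + yy * cos(ang))
      img[rows, cols] <- img[rows, cols] -
        amp * exp(-(u^2 / (2 * r^2) + v^2 / (2 * minor^2)))
    }
    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec@noiseSd), h, w)
    pmin(pmax(img, 0), 1)
  })
}

#' Generate a balanced, seeded synthetic dataset
#'
#' Renders \code{imagesPerClass} images per class with per-image seeds
#' derived from the master seed, and groups images into pseudo-patients
#' (5 images each) and pseudo-sections (10 images each) so patient-level
#' recognition rates and section-level majority votes can be exercised.
#' Regeneration with the same seed is bit-identical.
#'
#' @param specs list of \code{\linkS4class{ClassSpec}} (>= 2, unique names).
#' @param imagesPerClass images per class (>= 2).
#' @param seed master seed.
#' @param dim image height and width.
#' @return a \code{\linkS4class{SyntheticDataset}}.
#' @examples
#' ds <- generateDataset(defaultClassSpecs(), imagesPerClass = 2, seed = 1,
#'                       dim = c(64, 64))
#' ds
#' @export
generateDataset <- function(specs = defaultClassSpecs(), imagesPerClass = 40L,
                            seed = 0L, dim = c(300L, 300L)) {
  if (length(specs) < 2) stop("at least 2 class specs are required")
  names <- vapply(specs, function(s) s@name, character(1))
  if (anyDuplicated(names))
    stop(sprintf("duplicate class name: %s", names[duplicated(names)][1]))
  imagesPerClass <- as.integer(imagesPerClass)
  if (imagesPerClass < 2) stop("imagesPerClass must be >= 2")
  images <- list(); labels <- character(); patient <- character()
  section <- character()
  pCount <- 0L; sCount <- 0L
  for (ci in seq_along(specs)) {
    for (i in seq_len(imagesPerClass)) {
      s <- .deriveSeed(seed, paste0("image-", names[ci], "-", i))
      images[[length(images) + 1L]] <- renderImage(specs[[ci]], s, dim)
      labels <- c(labels, names[ci])
      patient <- c(patient, sprintf("P%03d", pCount + (i - 1L) %/% 5L + 1L))
      section <- c(section, sprintf("S%03d", sCount + (i - 1L) %/% 10L + 1L))
    }
    pCount <- pCount + ceiling(imagesPerClass / 5)
    sCount <- sCount + ceiling(imagesPerClass / 10)
  }
  new("SyntheticDataset", images = images, labels = labels,
      patient = patient, section = section, seed = as.integer(seed),
      specs = specs)
}

#' Colorize a grayscale synthetic tile with an H&E-like palette
#'
#' Maps dark blob interiors to haematoxylin purple and the light background
#' to eosin pink, producing an RGB array; exists to exercise the RGB to
#' grayscale conversion path of the image loader.
#'
#' @param img grayscale matrix in [0, 1].
#' @return h x w x 3 numeric array in [0, 1].
#' @export
heColorize <- function(img) {
  nucleus <- c(0.42, 0.22, 0.60)   # purple
  background <- c(0.95, 0.80, 0.88)  # pink
  out <- array(0, c(dim(img), 3L))
  for (ch in 1:3)
    out[, , ch] <- nucleus[ch] + (background[ch] - nucleus[ch]) * img
  out
}

#' Write a synthetic dataset to disk with a manifest
#'
#' Saves each image as a PNG under \code{dir} and writes
#' \code{manifest.csv} with columns \code{path}, \code{label},
#' \code{patient_id}, \code{section_id}, \code{seed}.
#'
#' @param dataset a \code{\linkS4class{SyntheticDataset}}.
#' @param dir output directory (created if needed).
#' @param color write H&E-colorized RGB PNGs instead of grayscale.
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(dataset, dir, color = FALSE) {
  stopifnot(is(dataset, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset@images)
  within <- stats::ave(seq_len(n), dataset@labels, FUN = seq_along)
  paths <- character(n)
  seeds <- integer(n)
  for (i in seq_len(n)) {
    seeds[i] <- .deriveSeed(dataset@seed,
                            paste0("image-", dataset@labels[i], "-",
                                   within[i]))
    paths[i] <- file.path(dir, sprintf("%s_%03d.png", dataset@labels[i],
                                       within[i]))
    img <- dataset@images[[i]]
    png::writePNG(if (color) heColorize(img) else img, paths[i])
  }
  manifest <- data.frame(path = paths, label = dataset@labels,
                         patient_id = dataset@patient,
                         section_id = dataset@section, seed = seeds)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
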