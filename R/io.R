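# Image and manifest I/O, run configuration, stratified splitting and the
# one-axis-at-a-time parameter tuning protocol.

#' Load an image file as a grayscale matrix in [0, 1]
#'
#' Reads PNG, TIFF or JPEG; 8/16-bit integer data are rescaled to [0, 1] by
#' the decoders.  RGB(A) images are converted to luminance with the ITU-R
#' BT.601 weights 0.299 R + 0.587 G + 0.114 B; the alpha channel is ignored.
#' Pixels are read as stored in the raster.
#'
#' @param path image file path.
#' @return numeric matrix in [0, 1].
#' @export
loadImageAsGray <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: '%s'", path))
  ext <- tolower(sub(".*\\.", "", basename(path)))
  raw <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '.%s'", ext))),
    error = function(e)
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e))))
  grayFromArray(raw, path)
}

#' @rdname loadImageAsGray
#' @param pixels numeric matrix (grayscale) or h x w x channels array.
#' @export
grayFromArray <- function(pixels, path = "<array>") {
  if (is.matrix(pixels)) {
    img <- pixels
  } else if (is.array(pixels) && length(dim(pixels)) == 3) {
    nc <- dim(pixels)[3]
    if (nc == 1) img <- pixels[, , 1]
    else if (nc %in% c(3, 4))
      img <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] +
             0.114 * pixels[, , 3]
    else if (nc == 2) img <- pixels[, , 1]      # gray + alpha
    else stop(sprintf("'%s': unsupported channel count %d", path, nc))
  } else {
    stop(sprintf("'%s': unsupported pixel layout", path))
  }
  if (!all(is.finite(img)) || min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop(sprintf("'%s': intensities outside [0, 1]", path))
  pmin(pmax(img, 0), 1)
}

#' Read and write image manifests
#'
#' A manifest is a CSV with columns \code{path}, \code{label} and optional
#' \code{patient_id}, \code{section_id} (and \code{seed}).  Relative paths
#' are resolved against the manifest's directory.
#'
#' @param path manifest file.
#' @param requireExists verify that every image file exists.
#' @return data.frame with the manifest rows.
#' @export
readManifest <- function(path, requireExists = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop(sprintf("manifest '%s' must have columns path, label", path))
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  if (requireExists && !all(file.exists(m$path)))
    stop(sprintf("manifest '%s': %d image file(s) missing, e.g. '%s'", path,
                 sum(!file.exists(m$path)), m$path[!file.exists(m$path)][1]))
  m
}

#' @rdname readManifest
#' @param manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split of a manifest
#'
#' Allocates each class proportionally to the requested fractions
#' (validation and test sizes are rounded down; the remainder goes to
#' training), with a seeded shuffle, so the three subsets are disjoint and
#' reproducible.  With \code{byPatient = TRUE} whole patients are allocated
#' instead of single images, so no patient straddles subsets.
#'
#' @param manifest data.frame with at least \code{label} (and
#'   \code{patient_id} for patient-disjoint mode).
#' @param fractions three proportions summing to 1 (train, validation,
#'   test); default 0.6/0.2/0.2.
#' @param seed integer seed.
#' @param byPatient keep each patient's images in a single subset.
#' @return named list of three data.frames: \code{train},
#'   \code{validation}, \code{test}.
#' @export
stratifiedSplit <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 0L,
                            byPatient = FALSE) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")
  if (length(fractions) != 3) stop("three fractions are required")
  small <- names(which(table(manifest$label) < 3))
  if (length(small))
    stop(sprintf("class '%s' has fewer than 3 images; cannot split",
                 small[1]))
  parts <- list(train = integer(), validation = integer(), test = integer())
  .withSeed(.deriveSeed(seed, "split"), {
    for (cls in sort(unique(manifest$label))) {
      idx <- which(manifest$label == cls)
      if (byPatient) {
        pats <- sample(unique(manifest$patient_id[idx]))
        sizes <- .splitSizes(length(pats), fractions)
        assign <- split(pats, rep(names(parts), sizes))
        for (p in names(parts))
          parts[[p]] <- c(parts[[p]],
                          idx[manifest$patient_id[idx] %in% assign[[p]]])
      } else {
        idx <- sample(idx)
        sizes <- .splitSizes(length(idx), fractions)
        assign <- split(idx, rep(names(parts), sizes))
        for (p in names(parts))
          parts[[p]] <- c(parts[[p]], assign[[p]])
      }
    }
  })
  lapply(parts, function(i) manifest[sort(i), , drop = FALSE])
}

# validation/test floor allocation, remainder to training
.splitSizes <- function(n, fractions) {
  nVal <- floor(n * fractions[2])
  nTest <- floor(n * fractions[3])
  c(train = n - nVal - nTest, validation = nVal, test = nTest)
}

#' Assemble and validate a run configuration
#'
#' Collects every tunable of the pipeline with its default so a run can log
#' the fully resolved configuration: detector parameters, codebook size and
#' seed, kernel, split fractions (0.6/0.2/0.2 mirroring a 623/211/209-style
#' division), number of repeated trials and the master seed from which all
#' named random substreams (split / codebook / SVM / synthesis) are derived.
#'
#' @param sift a \code{\link{siftParams}} object.
#' @param codebookSize codebook size k.
#' @param kernel a \code{\link{kernelSpec}}.
#' @param fractions train/validation/test proportions.
#' @param trials repeated random-split trials (>= 1).
#' @param seed master seed.
#' @return validated configuration list of class \code{histosift_config}.
#' @export
runConfig <- function(sift = siftParams(), codebookSize = 500L,
                      kernel = kernelSpec(), fractions = c(0.6, 0.2, 0.2),
                      trials = 10L, seed = 0L) {
  validObject(sift); validObject(kernel)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (trials < 1) stop("trials must be >= 1")
  structure(list(sift = sift, codebookSize = as.integer(codebookSize),
                 kernel = kernel, fractions = fractions,
                 trials = as.integer(trials), seed = as.integer(seed)),
            class = "histosift_config")
}

#' @rdname runConfig
#' @param config a \code{histosift_config}.
#' @param con connection or path for the resolved-configuration log.
#' @export
logConfig <- function(config, con = stdout()) {
  s <- config$sift
  lines <- c(
    "# histosift resolved run configuration",
    sprintf("sift.sigma0 = %g", s@sigma0),
    sprintf("sift.contrast_threshold = %g", s@contrastThreshold),
    sprintf("sift.edge_threshold = %g", s@edgeThreshold),
    sprintf("sift.intervals = %d", s@intervals),
    sprintf("sift.n_octaves = %s",
            if (is.na(s@nOctaves)) "auto" else as.character(s@nOctaves)),
    sprintf("sift.upsample = %s", tolower(as.character(s@upsample))),
    sprintf("codebook.size = %d", config$codebookSize),
    sprintf("kernel.kind = %s", config$kernel@kind),
    sprintf("kernel.gamma = %g", config$kernel@gamma),
    sprintf("kernel.C = %g", config$kernel@cost),
    sprintf("split.fractions = %s", paste(config$fractions, collapse = "/")),
    sprintf("trials = %d", config$trials),
    sprintf("seed = %d", config$seed))
  if (is.character(con)) writeLines(lines, con) else writeLines(lines, con)
  invisible(lines)
}

#' Train the full pipeline on labelled images
#'
#' Extracts scale-invariant features from every training image, clusters
#' them into a codebook, encodes each image as a bag-of-features histogram
#' (flat or spatial pyramid) and trains the one-vs-one SVM.
#'
#' @param images list of grayscale matrices.
#' @param labels class label per image.
#' @param params \code{\link{siftParams}}.
#' @param codebookSize codebook size k.
#' @param kernel \code{\link{kernelSpec}}.
#' @param pyramid spatial-pyramid levels; 1 = flat bag of features.
#' @param seed master seed for the codebook substream.
#' @param features optional precomputed list of
#'   \code{\linkS4class{SiftFeatures}} (skips extraction).
#' @return list of class \code{histosift_fit} with the model, codebook,
#'   parameters and encoding settings.
#' @export
trainImageClassifier <- function(images, labels, params = siftParams(),
                                 codebookSize = 500L,
                                 kernel = kernelSpec(), pyramid = 1L,
                                 seed = 0L, features = NULL) {
  if (is.null(features))
    features <- lapply(images, extractFeatures, params = params)
  labels <- as.character(labels)
  nkp <- vapply(features, length, integer(1))
  if (any(nkp == 0)) {
    warning(sprintf("dropping %d training image(s) that yielded no features",
                    sum(nkp == 0)))
    features <- features[nkp > 0]
    labels <- labels[nkp > 0]
  }
  if (length(features) == 0) stop("no training images with features remain")
  cb <- buildCodebook(features, k = codebookSize,
                      seed = .deriveSeed(seed, "codebook"))
  H <- t(vapply(features, function(f)
    if (pyramid > 1) encodePyramid(f, cb, levels = pyramid)
    else encodeBof(f, cb),
    numeric(codebookSize * sum(4^(0:(pyramid - 1)))) ))
  model <- trainHistoSvm(H, labels, spec = kernel,
                         seed = .deriveSeed(seed, "svm"), codebook = cb)
  structure(list(model = model, codebook = cb, params = params,
                 pyramid = as.integer(pyramid)),
            class = "histosift_fit")
}

#' Predict labels for new images with a fitted pipeline
#'
#' @param fit result of \code{\link{trainImageClassifier}}.
#' @param images list of grayscale matrices.
#' @param features optional precomputed \code{\linkS4class{SiftFeatures}}.
#' @return list with \code{label}, \code{votes}, \code{scores} (images
#'   without any features get \code{NA} labels and zero scores).
#' @export
predictImages <- function(fit, images, features = NULL) {
  stopifnot(inherits(fit, "histosift_fit"))
  if (is.null(features))
    features <- lapply(images, extractFeatures, params = fit$params)
  k <- codebookSize(fit$codebook)
  dims <- k * sum(4^(0:(fit$pyramid - 1)))
  ok <- vapply(features, length, integer(1)) > 0
  H <- matrix(0, length(features), dims)
  for (i in which(ok))
    H[i, ] <- if (fit$pyramid > 1)
      encodePyramid(features[[i]], fit$codebook, levels = fit$pyramid)
    else encodeBof(features[[i]], fit$codebook)
  pred <- predict(fit$model, H)
  if (any(!ok)) {
    pred$label[!ok] <- NA_character_
    pred$votes[!ok, ] <- 0
    pred$scores[!ok, ] <- 0
    warning(sprintf("%d image(s) yielded no features; labels set to NA",
                    sum(!ok)))
  }
  pred
}

#' One-axis-at-a-time parameter tuning
#'
#' Sweeps the detector and codebook parameters one axis at a time in the
#' order sigma0, contrast threshold, edge threshold, codebook size; each
#' grid cell is scored by mean held-out accuracy over \code{repeats} seeded
#' random sub-splits of the supplied validation images (by default roughly
#' 150/61, i.e. 71% train / 29% eval).  After each axis the best value is
#' fixed before sweeping the next, mirroring a sequential tuning protocol;
#' \code{fullFactorial = TRUE} evaluates the complete grid instead.
#'
#' @param images list of grayscale matrices (the validation images).
#' @param labels class label per image.
#' @param config a \code{\link{runConfig}} supplying defaults and the seed.
#' @param grids named list of candidate values for \code{sigma0},
#'   \code{contrastThreshold}, \code{edgeThreshold}, \code{codebookSize}.
#' @param repeats sub-split repeats per cell.
#' @param subFraction training share of each sub-split.
#' @param fullFactorial evaluate the cross product of all axes.
#' @return data.frame with one row per evaluated cell: axis, value, mean
#'   and sd of accuracy, repeats; attribute \code{best} holds the selected
#'   parameter set.
#' @export
tuneGrid <- function(images, labels, config = runConfig(),
                     grids = list(sigma0 = c(0.1, 0.5, 0.9, 1.3, 1.7, 2.1),
                                  contrastThreshold = c(0.02, 0.03, 0.04,
                                                        0.05, 0.06),
                                  edgeThreshold = c(5, 11, 17, 23, 29),
                                  codebookSize = c(300, 400, 500, 600, 700)),
                     repeats = config$trials, subFraction = 150 / 211,
                     fullFactorial = FALSE) {
  if (length(images) == 0) stop("validation set is empty")
  for (axis in names(grids)) .checkGridAxis(axis, grids[[axis]])
  current <- list(sigma0 = config$sift@sigma0,
                  contrastThreshold = config$sift@contrastThreshold,
                  edgeThreshold = config$sift@edgeThreshold,
                  codebookSize = config$codebookSize)
  cells <- if (fullFactorial) {
    grid <- expand.grid(grids, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ]))
  } else NULL

  rows <- list()
  evalCell <- function(vals) {
    accs <- vapply(seq_len(repeats), function(r) {
      .tuneTrialAccuracy(images, labels, vals, config, r, subFraction)
    }, numeric(1))
    c(mean = mean(accs), sd = stats::sd(accs))
  }
  if (fullFactorial) {
    best <- NULL; bestAcc <- -1
    for (vals in cells) {
      st <- evalCell(vals)
      rows[[length(rows) + 1L]] <-
        data.frame(axis = "factorial",
                   value = paste(unlist(vals), collapse = "/"),
                   meanAccuracy = st["mean"], sdAccuracy = st["sd"],
                   repeats = repeats)
      if (st["mean"] > bestAcc) { bestAcc <- st["mean"]; best <- vals }
    }
    current <- best
  } else {
    for (axis in c("sigma0", "contrastThreshold", "edgeThreshold",
                   "codebookSize")) {
      if (is.null(grids[[axis]])) next
      accs <- vapply(grids[[axis]], function(v) {
        vals <- current; vals[[axis]] <- v
        st <- evalCell(vals)
        rows[[length(rows) + 1L]] <<-
          data.frame(axis = axis, value = as.character(v),
                     meanAccuracy = st["mean"], sdAccuracy = st["sd"],
                     repeats = repeats)
        st["mean"]
      }, numeric(1))
      current[[axis]] <- grids[[axis]][which.max(accs)]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "best") <- current
  out
}

.checkGridAxis <- function(axis, values) {
  ok <- switch(axis,
    sigma0 = all(values > 0),
    contrastThreshold = all(values > 0),
    edgeThreshold = all(values >= 1),
    codebookSize = all(values >= 2),
    stop(sprintf("unknown tuning axis '%s'", axis)))
  if (!ok) stop(sprintf("invalid value(s) in tuning grid for '%s'", axis))
  invisible(TRUE)
}

.tuneTrialAccuracy <- function(images, labels, vals, config, trial,
                               subFraction) {
  n <- length(images)
  idx <- .withSeed(.deriveSeed(config$seed, paste0("tune-trial-", trial)), {
    unlist(lapply(split(seq_len(n), labels), function(ix) {
      ntr <- max(1L, round(length(ix) * subFraction))
      sample(ix)[seq_len(min(ntr, length(ix) - 1L))]
    }), use.names = FALSE)
  })
  params <- siftParams(sigma0 = vals$sigma0,
                       contrastThreshold = vals$contrastThreshold,
                       edgeThreshold = vals$edgeThreshold,
                       nOctaves = config$sift@nOctaves,
                       intervals = config$sift@intervals,
                       upsample = config$sift@upsample)
  fit <- tryCatch(
    trainImageClassifier(images[idx], labels[idx], params = params,
                         codebookSize = vals$codebookSize,
                         kernel = config$kernel,
                         seed = .deriveSeed(config$seed,
                                            paste0("tune-fit-", trial))),
    error = function(e) NULL)
  if (is.null(fit)) return(0)
  hold <- setdiff(seq_len(n), idx)
  pred <- predictImages(fit, images[hold])
  mean(pred$label == labels[hold], na.rm = TRUE)
}
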