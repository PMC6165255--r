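# Bag-of-features encoding: k-means codebook over 128-d descriptors and
# L1-normalized codeword-occurrence histograms (flat or spatial pyramid).

# Nearest centroid per row of X (chunked BLAS; ties -> lowest index).
# Returns list(cluster, dist2).
.nearestCentroid <- function(X, C, chunk = 8192L) {
  n <- nrow(X)
  cl <- integer(n)
  d2 <- numeric(n)
  cn <- rowSums(C^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    G <- X[idx, , drop = FALSE] %*% t(C)            # n_c x k
    D <- sweep(-2 * G, 2L, cn, "+")                 # ||c||^2 - 2 x.c
    cl[idx] <- max.col(-D, ties.method = "first")
    d2[idx] <- D[cbind(seq_along(idx), cl[idx])] +
      rowSums(X[idx, , drop = FALSE]^2)
  }
  d2[d2 < 0] <- 0
  list(cluster = cl, dist2 = d2)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center drawn with probability proportional to squared distance
# to the nearest chosen center.
.kmeansPlusPlusInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  pick <- sample.int(n, 1L)
  centers[1L, ] <- X[pick, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    tot <- sum(d2)
    pick <- if (tot <= 0) sample.int(n, 1L) else
      findInterval(stats::runif(1) * tot, cumsum(d2)) + 1L
    pick <- min(pick, n)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

# Lloyd iterations; empty clusters are re-seeded with the currently
# worst-fitted points.  Converges when no assignment changes or maxIter hits.
.kmeansLloyd <- function(X, centers, maxIter = 300L) {
  k <- nrow(centers)
  prev <- integer(nrow(X))
  for (it in seq_len(maxIter)) {
    a <- .nearestCentroid(X, centers)
    if (identical(a$cluster, prev)) break
    prev <- a$cluster
    counts <- tabulate(a$cluster, k)
    sums <- rowsum(X, a$cluster)            # rows sorted by cluster id
    centers[sort(unique(a$cluster)), ] <- sums / counts[counts > 0]
    empty <- which(counts == 0L)
    if (length(empty)) {
      far <- order(a$dist2, decreasing = TRUE)[seq_along(empty)]
      centers[empty, ] <- X[far, , drop = FALSE]
    }
  }
  a <- .nearestCentroid(X, centers)
  list(centers = centers, cluster = a$cluster, wcss = sum(a$dist2),
       iterations = it)
}

#' Build a codeword codebook by k-means clustering of descriptors
#'
#' Clusters training descriptors into \code{k} centroids (the codewords)
#' with k-means: k-means++ initialization under a fixed seed, Lloyd updates
#' capped at 300 iterations, best of \code{restarts} restarts by
#' within-cluster sum of squares.  Deterministic for a fixed seed.  When the
#' descriptor pool exceeds \code{sampleCap} rows, a seeded uniform subsample
#' of that size is clustered to bound the cost.
#'
#' @param descriptors numeric matrix of 128-column descriptor rows (or a
#'   \code{\linkS4class{SiftFeatures}} object, or a list of either).
#' @param k codebook size; default 500, the size selected on held-out
#'   histology tiles.
#' @param seed integer clustering seed.
#' @param restarts independent restarts (best kept).
#' @param maxIter Lloyd iteration cap per restart.
#' @param sampleCap training-subsample cap.
#' @return a \code{\linkS4class{Codebook}}.
#' @export
buildCodebook <- function(descriptors, k = 500L, seed = 0L, restarts = 3L,
                          maxIter = 300L, sampleCap = 100000L) {
  X <- .asDescriptorMatrix(descriptors)
  k <- as.integer(k)
  if (k < 2) stop("codebook size k must be at least 2")
  if (nrow(X) < k)
    stop(sprintf("need at least k = %d descriptors, got %d", k, nrow(X)))
  if (nrow(X) > sampleCap) {
    X <- .withSeed(.deriveSeed(seed, "codebook-subsample"),
                   X[sample.int(nrow(X), sampleCap), , drop = FALSE])
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .withSeed(.deriveSeed(seed, paste0("codebook-restart-", r)), {
      init <- .kmeansPlusPlusInit(X, k)
      .kmeansLloyd(X, init, maxIter = maxIter)
    })
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  ctr <- best$centers
  dup <- duplicated(ctr)
  if (any(dup)) {
    # nudge exact duplicates apart deterministically; keeps k fixed
    ctr[dup, ] <- ctr[dup, , drop = FALSE] +
      1e-9 * seq_len(sum(dup))
  }
  new("Codebook", centroids = ctr, seed = as.integer(seed),
      inertia = best$wcss)
}

.asDescriptorMatrix <- function(descriptors) {
  if (is(descriptors, "SiftFeatures")) return(descriptors@descriptors)
  if (is.list(descriptors) && !is.data.frame(descriptors))
    return(do.call(rbind, lapply(descriptors, .asDescriptorMatrix)))
  X <- as.matrix(descriptors)
  if (ncol(X) != 128) stop("descriptors must have 128 columns")
  X
}

#' Encode descriptors as a bag-of-features histogram
#'
#' Assigns each descriptor to its nearest codeword (Euclidean distance,
#' ties to the lowest centroid index), counts occurrences per codeword and
#' L1-normalizes, so an image is represented by the relative frequencies of
#' its visual words.
#'
#' @param descriptors descriptor matrix or \code{\linkS4class{SiftFeatures}}.
#' @param codebook a \code{\linkS4class{Codebook}}.
#' @return numeric vector of length \code{codebookSize(codebook)} summing
#'   to 1.
#' @export
encodeBof <- function(descriptors, codebook) {
  stopifnot(is(codebook, "Codebook"))
  X <- .asDescriptorMatrix(descriptors)
  if (nrow(X) == 0) stop("no features extracted: cannot encode an empty set")
  a <- .nearestCentroid(X, codebook@centroids)
  counts <- tabulate(a$cluster, nrow(codebook@centroids))
  counts / sum(counts)
}

#' Encode features as a spatial-pyramid bag-of-features histogram
#'
#' Concatenates per-cell bag-of-features histograms over nested spatial
#' grids: level \code{l} divides the image into \code{2^l x 2^l} cells
#' (\code{l = 0 .. levels - 1}).  Each cell histogram is L1-normalized and
#' weighted by the pyramid-match weights \code{1 / 2^(L - l)} with the
#' level-0 weight halved (\code{L = levels - 1}); the concatenated vector is
#' L1-normalized.  \code{levels = 1} reduces exactly to
#' \code{\link{encodeBof}}.
#'
#' @param features a \code{\linkS4class{SiftFeatures}} object (keypoint
#'   coordinates place descriptors into cells).
#' @param codebook a \code{\linkS4class{Codebook}}.
#' @param levels number of pyramid levels (>= 1); default 2.
#' @param imageDim height and width; defaults to the source image of
#'   \code{features}.
#' @return numeric vector of length
#'   \code{codebookSize(codebook) * sum(4^(0:(levels-1)))}.
#' @export
encodePyramid <- function(features, codebook, levels = 2L,
                          imageDim = features@dim) {
  stopifnot(is(features, "SiftFeatures"), is(codebook, "Codebook"))
  levels <- as.integer(levels)
  if (levels < 1) stop("levels must be >= 1")
  if (length(features) == 0)
    stop("no features extracted: cannot encode an empty set")
  k <- nrow(codebook@centroids)
  a <- .nearestCentroid(features@descriptors, codebook@centroids)
  kp <- features@keypoints
  L <- levels - 1L
  blocks <- list()
  for (l in 0:L) {
    ncell <- 2^l
    cw <- imageDim[2] / ncell
    ch <- imageDim[1] / ncell
    cx <- pmin(floor(kp$x / cw), ncell - 1)
    cy <- pmin(floor(kp$y / ch), ncell - 1)
    cellId <- cy * ncell + cx + 1
    weight <- 2^(-(L - l))
    if (l == 0) weight <- weight / 2       # level-0 carries half weight
    for (cell in seq_len(ncell^2)) {
      counts <- tabulate(a$cluster[cellId == cell], k)
      tot <- sum(counts)
      blocks[[length(blocks) + 1L]] <-
        if (tot > 0) weight * counts / tot else numeric(k)
    }
  }
  v <- unlist(blocks, use.names = FALSE)
  v / sum(v)
}

#' Read and write codebooks as versioned text files
#'
#' Format: header line \code{#histosift-cb v1}, one line with \code{k} and
#' the clustering seed, then \code{k} lines of 128 numbers
#' (locale-independent decimal point, full double precision).
#'
#' @param codebook a \code{\linkS4class{Codebook}}.
#' @param path file path.
#' @return \code{writeCodebook}: \code{path} invisibly;
#'   \code{readCodebook}: the \code{\linkS4class{Codebook}}.
#' @export
writeCodebook <- function(codebook, path) {
  stopifnot(is(codebook, "Codebook"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#histosift-cb v1", con)
  writeLines(sprintf("%d %d", nrow(codebook@centroids), codebook@seed), con)
  apply(codebook@centroids, 1L, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con))
  invisible(path)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "#histosift-cb v1")
    stop(sprintf("'%s' is not a histosift-cb v1 codebook file", path))
  meta <- scan(text = lines[2], what = integer(), quiet = TRUE)
  k <- meta[1]
  ctr <- matrix(scan(text = lines[3:(2 + k)], what = double(), quiet = TRUE),
                nrow = k, ncol = 128, byrow = TRUE)
  new("Codebook", centroids = ctr, seed = meta[2], inertia = NA_real_)
}
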