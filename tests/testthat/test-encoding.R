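test_that("k-means recovers the means of well-separated clouds", {
  set.seed(7)
  a <- matrix(stats::rnorm(50 * 128, mean = 0, sd = 0.01), 50, 128)
  b <- matrix(stats::rnorm(50 * 128, mean = 1, sd = 0.01), 50, 128)
  cb <- buildCodebook(rbind(a, b), k = 2, seed = 3)
  ctr <- centroids(cb)[order(centroids(cb)[, 1]), ]
  expect_equal(unname(ctr[1, ]), unname(colMeans(a)), tolerance = 1e-6)
  expect_equal(unname(ctr[2, ]), unname(colMeans(b)), tolerance = 1e-6)
})

test_that("codebook construction is deterministic per seed and validates sizes", {
  set.seed(11)
  X <- matrix(stats::runif(400 * 128), 400, 128)
  cb1 <- buildCodebook(X, k = 10, seed = 5)
  cb2 <- buildCodebook(X, k = 10, seed = 5)
  expect_identical(centroids(cb1), centroids(cb2))
  cb3 <- buildCodebook(X, k = 10, seed = 6)
  expect_false(identical(centroids(cb1), centroids(cb3)))
  expect_error(buildCodebook(X[1:5, ], k = 10), "at least k = 10.*got 5")
})

test_that("k-means objective never increases with larger k (vs brute-force oracle)", {
  set.seed(21)
  X <- matrix(stats::runif(60 * 128), 60, 128)
  wcssOf <- function(X, ctr) {
    # brute-force assignment oracle: full distance matrix, explicit min
    d2 <- outer(rowSums(X^2), rowSums(ctr^2), "+") - 2 * X %*% t(ctr)
    sum(apply(d2, 1, min))
  }
  wcss <- vapply(c(2, 4, 8, 16), function(k) {
    cb <- buildCodebook(X, k = k, seed = 1)
    w <- wcssOf(X, centroids(cb))
    expect_equal(w, cb@inertia, tolerance = 1e-8)
    w
  }, numeric(1))
  expect_true(all(diff(wcss) <= 1e-8))
})

test_that("package k-means matches stats::kmeans from identical starts", {
  set.seed(31)
  X <- matrix(stats::rnorm(80 * 128), 80, 128)
  init <- X[1:4, ]
  ours <- histosift:::.kmeansLloyd(X, init, maxIter = 100)
  ref <- stats::kmeans(X, centers = init, iter.max = 100,
                       algorithm = "Lloyd")
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("bag-of-features histograms are L1-normalized counts of nearest codewords", {
  ctr <- diag(4)[, rep(1:4, length.out = 128)] * 0
  ctr <- matrix(0, 4, 128); ctr[cbind(1:4, 1:4)] <- 1
  cb <- new("Codebook", centroids = ctr, seed = 0L, inertia = 0)
  one <- matrix(0, 1, 128); one[1, 2] <- 1        # nearest centroid 2
  expect_equal(encodeBof(one, cb), c(0, 1, 0, 0))
  ten <- matrix(0, 10, 128); ten[, 3] <- 1        # all nearest centroid 3
  expect_equal(encodeBof(ten, cb), c(0, 0, 1, 0))
  expect_error(encodeBof(matrix(0, 0, 128), cb), "no features")
})

test_that("histograms sum to 1, are order-invariant and conserve mass", {
  set.seed(5)
  cb <- buildCodebook(matrix(stats::runif(200 * 128), 200, 128), k = 16,
                      seed = 2)
  for (i in 1:10) {
    X <- matrix(stats::runif(50 * 128), 50, 128)
    h <- encodeBof(X, cb)
    expect_equal(sum(h), 1, tolerance = 1e-9)
    expect_true(all(h >= 0))
    expect_equal(encodeBof(X[sample(50), ], cb), h)
    # pre-normalization mass equals the descriptor count
    a <- histosift:::.nearestCentroid(X, centroids(cb))
    expect_equal(sum(tabulate(a$cluster, 16)), 50)
  }
})

test_that("nearest-centroid ties go to the lowest index", {
  ctr <- matrix(0, 3, 128)
  ctr[2, 1] <- 1; ctr[3, 1] <- 1
  ctr[2, 2] <- 0.25; ctr[3, 2] <- -0.25   # exactly equidistant from x
  cb <- new("Codebook", centroids = ctr, seed = 0L, inertia = 0)
  x <- matrix(0, 1, 128); x[1, 1] <- 1
  h <- encodeBof(x, cb)
  expect_equal(which(h > 0), 2)
})

test_that("spatial pyramid reduces to the flat histogram at one level", {
  img <- fixture("blob96", blobImage())
  fts <- fixture("blob96feats", extractFeatures(img))
  cb <- fixture("cb16", buildCodebook(matrix(stats::runif(300 * 128),
                                             300, 128), k = 16, seed = 9))
  expect_equal(encodePyramid(fts, cb, levels = 1),
               encodeBof(descriptors(fts), cb), tolerance = 1e-12)
  h2 <- encodePyramid(fts, cb, levels = 2)
  expect_length(h2, 16 * 5)                        # k * (1 + 4) cells
  expect_equal(sum(h2), 1, tolerance = 1e-9)
})

test_that("quadrant cells without keypoints give zero blocks", {
  img <- fixture("blob96", blobImage())
  fts <- fixture("blob96feats", extractFeatures(img))
  cb <- fixture("cb16", buildCodebook(matrix(stats::runif(300 * 128),
                                             300, 128), k = 16, seed = 9))
  # squeeze all keypoints into the top-left quadrant
  sq <- fts
  sq@keypoints$x <- sq@keypoints$x / 3
  sq@keypoints$y <- sq@keypoints$y / 3
  h <- encodePyramid(sq, cb, levels = 2)
  blocks <- split(h, rep(1:5, each = 16))
  expect_gt(sum(blocks[[1]]), 0)       # level-0 block
  expect_gt(sum(blocks[[2]]), 0)       # top-left cell
  expect_equal(sum(blocks[[3]]), 0)
  expect_equal(sum(blocks[[4]]), 0)
  expect_equal(sum(blocks[[5]]), 0)
})

test_that("codebooks round-trip through the versioned text format", {
  cb <- fixture("cb16", buildCodebook(matrix(stats::runif(300 * 128),
                                             300, 128), k = 16, seed = 9))
  path <- withr::local_tempfile(fileext = ".cb")
  writeCodebook(cb, path)
  expect_equal(readLines(path, n = 1), "#histosift-cb v1")
  back <- readCodebook(path)
  expect_identical(centroids(back), unname(centroids(cb)))
  expect_equal(back@seed, cb@seed)
})
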