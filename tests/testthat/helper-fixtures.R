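# Shared fixtures, generated in code and cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# A small blob texture with plenty of structure.
blobImage <- function(seed = 2, dim = c(96, 96), density = 8) {
  renderImage(classSpec("fix", radiusMean = 4, radiusSd = 1,
                        density = density, contrast = 0.9,
                        noiseSd = 0.02, jitterRange = c(1, 1)),
              seed = seed, dim = dim)
}

# Analytic isotropic Gaussian blob centred in the frame.
analyticBlob <- function(n = 64, sigma = 4, amp = 0.5) {
  ctr <- (n - 1) / 2
  d2 <- outer((0:(n - 1) - ctr)^2, (0:(n - 1) - ctr)^2, "+")
  0.5 + amp * exp(-d2 / (2 * sigma^2)) - amp / 2
}

# Rotate a matrix by 90 degrees counterclockwise (lossless).
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Map keypoint (x, y) through the same 90-degree rotation; n = ncol(image).
rot90xy <- function(kp, n) cbind(x = kp$y, y = (n - 1) - kp$x)

# Best-candidate descriptor match rate between two feature sets under a
# coordinate map: a keypoint matches when some keypoint within tolPx pixels
# and one scale interval has descriptor cosine >= minCos.
descriptorMatchRate <- function(f1, f2, mapped, tolPx = 1.5, minCos = 0.9) {
  kp1 <- keypoints(f1); kp2 <- keypoints(f2)
  if (nrow(kp1) == 0) return(NA_real_)
  hits <- vapply(seq_len(nrow(kp1)), function(i) {
    cand <- which(sqrt((kp2$x - mapped[i, 1])^2 +
                       (kp2$y - mapped[i, 2])^2) <= tolPx &
                  abs(log2(kp2$sigma / kp1$sigma[i])) <= 1 / 3 + 1e-9)
    length(cand) > 0 &&
      max(descriptors(f2)[cand, , drop = FALSE] %*%
            descriptors(f1)[i, ]) >= minCos
  }, logical(1))
  mean(hits)
}

# Independent brute-force 26-neighbor extremum oracle on a 3-level stack.
bruteForceExtrema <- function(below, mid, above) {
  h <- nrow(mid); w <- ncol(mid)
  out <- NULL
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    v <- mid[r, c]
    neigh <- c(below[(r - 1):(r + 1), (c - 1):(c + 1)],
               above[(r - 1):(r + 1), (c - 1):(c + 1)],
               mid[(r - 1):(r + 1), (c - 1):(c + 1)][-5])
    if (all(v > neigh) || all(v < neigh))
      out <- rbind(out, c(row = r - 1L, col = c - 1L))
  }
  out
}

# Independent weighted-metrics oracle (direct formulas, no shared code).
bruteForceMetrics <- function(actual, predicted, classes) {
  pcs <- t(vapply(classes, function(cl) {
    tp <- sum(actual == cl & predicted == cl)
    fp <- sum(actual != cl & predicted == cl)
    fn <- sum(actual == cl & predicted != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(support = sum(actual == cl), precision = p, recall = r, f = f)
  }, numeric(4)))
  w <- pcs[, "support"] / sum(pcs[, "support"])
  c(precision = sum(w * pcs[, "precision"]),
    recall = sum(w * pcs[, "recall"]), f = sum(w * pcs[, "f"]))
}
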