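# Internal helpers: seeded RNG scoping and input validation.

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Named substream derivation: every source of randomness draws its seed from
# the master seed plus a purpose string, so runs are reproducible end to end
# and substreams are decoupled.  Arithmetic stays below 2^53, result < 2^31.
.deriveSeed <- function(master, purpose) {
  m <- 2147483647  # 2^31 - 1
  h <- (as.numeric(master) %% m) + 1
  for (b in utf8ToInt(as.character(purpose))) h <- (h * 131 + b) %% m
  as.integer((h * 48271) %% m)
}

# A grayscale image is a finite numeric matrix with intensities in [0, 1].
.checkGray <- function(image, minSize = 32L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (nrow(image) < minSize || ncol(image) < minSize)
    stop(sprintf("image must be at least %dx%d pixels for feature extraction",
                 minSize, minSize))
  if (!all(is.finite(image)))
    stop("image contains non-finite intensities")
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image intensities must lie in [0, 1]")
  invisible(image)
}

# Short fingerprint of a codebook (order-sensitive moment digest); used to
# tie a trained model back to the codebook it was fitted with.
.codebookHash <- function(cb) {
  ctr <- cb@centroids
  idx <- seq_len(nrow(ctr))
  sprintf("cb:k=%d;seed=%d;s1=%.10e;s2=%.10e;sw=%.10e",
          nrow(ctr), cb@seed, sum(ctr), sum(ctr^2),
          sum(ctr * idx))
}
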