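# One-vs-one soft-margin SVM over bag-of-features histograms, with the RBF
# and histogram-intersection kernels supplied to the solver as precomputed
# Gram matrices.  kernlab's C-svc solves each binary subproblem; the pairing,
# decision aggregation, tie-breaking and serialization live here.

#' Kernel value between two histograms
#'
#' \code{rbf}: \code{exp(-gamma * ||a - b||^2)}; \code{histogram_intersection}:
#' \code{sum(pmin(a, b))}.  Both are symmetric; \code{K(a, a)} is 1 for the
#' RBF kernel and the L1 mass of \code{a} for the intersection kernel.
#'
#' @param a,b numeric histograms of equal length.
#' @param spec a \code{\link{kernelSpec}}.
#' @return a scalar kernel value.
#' @examples
#' kernelValue(c(0.2, 0.8), c(0.6, 0.4), kernelSpec("histogram_intersection"))
#' @export
kernelValue <- function(a, b, spec = kernelSpec()) {
  validObject(spec)
  if (length(a) != length(b))
    stop(sprintf("histogram lengths differ: %d vs %d", length(a), length(b)))
  if (spec@kind == "rbf") exp(-spec@gamma * sum((a - b)^2))
  else sum(pmin(a, b))
}

#' Gram matrix between two sets of histograms
#'
#' @param A,B numeric matrices with one histogram per row (\code{B}
#'   defaults to \code{A}).
#' @param spec a \code{\link{kernelSpec}}.
#' @return \code{nrow(A) x nrow(B)} kernel matrix.
#' @export
gramMatrix <- function(A, B = A, spec = kernelSpec()) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop(sprintf("histogram lengths differ: %d vs %d", ncol(A), ncol(B)))
  if (spec@kind == "rbf") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    exp(-spec@gamma * d2)
  } else {
    cpp_intersection_gram(A, B)
  }
}

#' Train a one-vs-one SVM on bag-of-features histograms
#'
#' Fits a soft-margin SVM for every unordered pair of classes on the
#' precomputed Gram matrix of the chosen kernel and stores the support
#' coefficients, offsets and training histograms needed to score new
#' histograms.  Deterministic for fixed inputs.
#'
#' @param histograms numeric matrix, one histogram per row.
#' @param labels class label per row (at least 2 classes, each with at
#'   least 2 examples).
#' @param spec a \code{\link{kernelSpec}}.
#' @param seed integer recorded with the model (the solver itself is
#'   deterministic).
#' @param codebook optional \code{\linkS4class{Codebook}} whose fingerprint
#'   is stored for provenance checks.
#' @return a \code{\linkS4class{HistoSvmModel}}.
#' @export
trainHistoSvm <- function(histograms, labels, spec = kernelSpec(), seed = 0L,
                          codebook = NULL) {
  H <- as.matrix(histograms)
  labels <- as.character(labels)
  if (nrow(H) != length(labels))
    stop("histogram and label counts differ")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("at least 2 classes are required")
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop(sprintf("class '%s' has fewer than 2 examples", small[1]))
  K <- gramMatrix(H, H, spec)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    idx <- which(labels %in% pr)
    y <- factor(labels[idx], levels = pr)
    Ksub <- K[idx, idx, drop = FALSE]
    fit <- .withSeed(.deriveSeed(seed, paste0("svm-", pr[1], "-", pr[2])),
      kernlab::ksvm(kernlab::as.kernelMatrix(Ksub), y, type = "C-svc",
                    C = spec@cost, kernel = "matrix"))
    ai <- kernlab::alphaindex(fit)[[1]]
    co <- kernlab::coef(fit)[[1]]
    b <- kernlab::b(fit)
    dec <- as.numeric(Ksub[, ai, drop = FALSE] %*% co - b)
    # resolve which side of the decision function each label occupies
    posLabel <- if (mean(dec[y == pr[1]]) >= mean(dec[y == pr[2]]))
      pr[1] else pr[2]
    list(pair = pr, svIndex = idx[ai], coef = co, b = b,
         posLabel = posLabel)
  })
  new("HistoSvmModel", kernel = spec, labels = classes, machines = machines,
      trainHistograms = H,
      codebookHash = if (is.null(codebook)) NA_character_
                     else .codebookHash(codebook))
}

#' Predict class labels for histograms
#'
#' Scores each histogram with every pairwise machine, accumulates one vote
#' per machine and a signed decision value per class, and returns the
#' plurality label.  Vote ties are broken by the larger summed per-class
#' decision score, then lexicographically.  Batch prediction equals
#' row-by-row prediction.
#'
#' @param object a \code{\linkS4class{HistoSvmModel}}.
#' @param newdata numeric histogram (vector) or matrix of histogram rows.
#' @param ... ignored.
#' @return list with \code{label} (character vector), \code{votes} and
#'   \code{scores} (numeric matrices, one column per class).
#' @export
setMethod("predict", "HistoSvmModel", function(object, newdata, ...) {
  H <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (ncol(H) != ncol(object@trainHistograms))
    stop(sprintf("histogram length %d does not match training length %d",
                 ncol(H), ncol(object@trainHistograms)))
  n <- nrow(H)
  classes <- object@labels
  votes <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  scores <- votes
  for (m in object@machines) {
    Krow <- gramMatrix(H, object@trainHistograms[m$svIndex, , drop = FALSE],
                       object@kernel)
    dec <- as.numeric(Krow %*% m$coef - m$b)
    pos <- m$posLabel
    neg <- setdiff(m$pair, pos)
    winner <- ifelse(dec >= 0, pos, neg)
    votes[cbind(seq_len(n), match(winner, classes))] <-
      votes[cbind(seq_len(n), match(winner, classes))] + 1
    scores[, pos] <- scores[, pos] + dec
    scores[, neg] <- scores[, neg] - dec
  }
  label <- vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    top <- names(v)[v == max(v)]
    if (length(top) > 1) {
      s <- scores[i, top]
      top <- top[s == max(s)]
      top <- sort(top)[1]   # lexicographic last resort
    }
    top
  }, character(1))
  list(label = label, votes = votes, scores = scores)
})

#' Read and write trained models as versioned text archives
#'
#' A single JSON file with format tag \code{histosift-model v1} holding the
#' kernel specification, class labels, codebook fingerprint, per-pair
#' support coefficients and the training histograms.  Numbers are written
#' with 17 significant digits, so a model round-trips bit-identically.
#'
#' @param model a \code{\linkS4class{HistoSvmModel}}.
#' @param path file path.
#' @return \code{writeModel}: \code{path} invisibly; \code{readModel}: the
#'   model.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "HistoSvmModel"))
  payload <- list(
    format = "histosift-model v1",
    kernel = list(kind = model@kernel@kind, gamma = model@kernel@gamma,
                  C = model@kernel@cost),
    labels = model@labels,
    codebookHash = model@codebookHash,
    machines = lapply(model@machines, function(m)
      list(pair = m$pair, svIndex = m$svIndex, coef = m$coef, b = m$b,
           posLabel = m$posLabel)),
    trainHistograms = model@trainHistograms)
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE),
             path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                          simplifyDataFrame = FALSE)
  if (!identical(p$format, "histosift-model v1"))
    stop(sprintf("'%s' is not a histosift-model v1 file", path))
  machines <- lapply(p$machines, function(m)
    list(pair = as.character(m$pair), svIndex = as.integer(m$svIndex),
         coef = as.numeric(m$coef), b = as.numeric(m$b),
         posLabel = as.character(m$posLabel)))
  new("HistoSvmModel",
      kernel = kernelSpec(p$kernel$kind, gamma = p$kernel$gamma,
                          C = p$kernel$C),
      labels = as.character(p$labels), machines = machines,
      trainHistograms = as.matrix(p$trainHistograms),
      codebookHash = as.character(p$codebookHash))
}
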