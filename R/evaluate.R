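# Evaluation protocol: confusion matrix with support-weighted precision /
# recall / F-measure, paired t-tests over repeated trials, majority-vote
# section labelling and patient-level recognition rates.

#' Confusion matrix and weighted precision/recall/F-measure
#'
#' Per class: precision = TP / (TP + FP), recall = TP / (TP + FN), F the
#' harmonic mean of the two.  A class never predicted has precision 0 by
#' convention (with a warning).  Weighted metrics average the per-class
#' values weighted by actual-class support, so weighted recall equals
#' overall accuracy.
#'
#' @param actual,predicted label vectors of equal length.
#' @param classes declared class set (defaults to the labels observed in
#'   \code{actual} and \code{predicted}); a label outside it is an error.
#' @return an \code{\linkS4class{EvaluationReport}}.
#' @examples
#' evaluatePredictions(c("a", "a", "b", "b"), c("a", "a", "a", "b"))
#' @export
evaluatePredictions <- function(actual, predicted, classes = NULL) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (length(actual) != length(predicted) || length(actual) < 1)
    stop("actual and predicted must have equal positive length")
  if (is.null(classes)) classes <- sort(unique(c(actual, predicted)))
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad))
    stop(sprintf("label(s) outside the declared class set: %s",
                 paste(bad, collapse = ", ")))
  af <- factor(actual, levels = classes)
  pf <- factor(predicted, levels = classes)
  conf <- table(actual = af, predicted = pf)
  conf <- matrix(as.integer(conf), nrow = length(classes),
                 dimnames = list(actual = classes, predicted = classes))
  tp <- diag(conf)
  support <- rowSums(conf)
  predTot <- colSums(conf)
  if (any(predTot == 0 & support > 0))
    warning(sprintf("class(es) never predicted, precision set to 0: %s",
                    paste(classes[predTot == 0 & support > 0],
                          collapse = ", ")))
  precision <- ifelse(predTot > 0, tp / predTot, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  w <- support / sum(support)
  weighted <- c(precision = sum(w * precision), recall = sum(w * recall),
                f = sum(w * f), accuracy = sum(tp) / sum(conf))
  new("EvaluationReport", confusion = conf,
      perClass = data.frame(class = classes, support = as.integer(support),
                            precision = precision, recall = recall, f = f,
                            row.names = NULL),
      weighted = weighted)
}

#' Paired t-test between per-trial F-measures of two methods
#'
#' Two-sided paired t-test on matched trial results (e.g. the F-measures of
#' two pipelines over the same repeated random splits).
#'
#' @param a,b numeric vectors of per-trial scores, equal length >= 2.
#' @param alpha significance level (default 0.05).
#' @return list with \code{t}, \code{p} and \code{significant}
#'   (\code{p < alpha}).  When the paired differences have zero variance the
#'   t statistic is undefined: \code{p} is reported as 0 when the means
#'   differ and 1 otherwise, with \code{degenerate = TRUE} flagged.
#' @export
pairedTTest <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b) || length(a) < 2)
    stop("a and b must be equal-length vectors with at least 2 trials")
  d <- a - b
  if (stats::var(d) == 0) {
    p <- if (mean(d) != 0) 0 else 1
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)), p = p,
                significant = p < alpha, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, degenerate = FALSE)
}

#' Majority vote over sub-image labels
#'
#' Classifies a whole tissue section from the labels of its sub-images by
#' plurality vote.  Vote ties are broken by the larger summed per-class
#' decision score (classifier confidence), then by lexicographic label
#' order; both tie-breaks are logged.
#'
#' @param labels predicted label per sub-image (>= 1).
#' @param scores optional numeric matrix of per-class decision scores, one
#'   row per sub-image, columns named by class (as returned by
#'   \code{predict} on a \code{\linkS4class{HistoSvmModel}}).
#' @return list with \code{label} (winning class), \code{count} (its
#'   votes) and \code{tally} (the full vote table).
#' @examples
#' majorityVote(rep(c("poorly-differentiated", "differentiating"), c(4, 6)))
#' @export
majorityVote <- function(labels, scores = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 1) stop("at least one sub-image label is required")
  tally <- table(labels)
  top <- names(tally)[tally == max(tally)]
  if (length(top) > 1) {
    if (!is.null(scores) && all(top %in% colnames(scores))) {
      tot <- colSums(scores[, top, drop = FALSE])
      message(sprintf("majority vote tie between %s broken by decision score",
                      paste(top, collapse = ", ")))
      top <- top[tot == max(tot)]
    }
    if (length(top) > 1) {
      message(sprintf("majority vote tie between %s broken lexicographically",
                      paste(top, collapse = ", ")))
      top <- sort(top)
    }
    top <- top[1]
  }
  list(label = top, count = as.integer(tally[top]), tally = tally)
}

#' Patient-level recognition rate
#'
#' Per patient, the score is the fraction of that patient's images
#' classified correctly, \code{Nrec / NP}; the recognition rate is the mean
#' patient score over all patients.
#'
#' @param records data.frame with columns \code{patient}, \code{nImages}
#'   (NP >= 1) and \code{nCorrect} (0 <= Nrec <= NP), one row per patient.
#' @return the recognition rate in [0, 1].
#' @examples
#' recognitionRate(data.frame(patient = c("p1", "p2"), nImages = c(4, 2),
#'                            nCorrect = c(3, 1)))   # (0.75 + 0.5) / 2
#' @export
recognitionRate <- function(records) {
  need <- c("patient", "nImages", "nCorrect")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data.frame with patient, nImages, nCorrect")
  if (nrow(records) < 1) stop("at least one patient is required")
  if (any(records$nImages < 1))
    stop("every patient must have at least one image (NP >= 1)")
  if (any(records$nCorrect < 0 | records$nCorrect > records$nImages))
    stop("nCorrect must satisfy 0 <= Nrec <= NP")
  mean(records$nCorrect / records$nImages)
}

#' Summarize per-image predictions into patient records
#'
#' @param patient patient id per image.
#' @param correct logical per image (prediction equals truth).
#' @return data.frame suitable for \code{\link{recognitionRate}}.
#' @export
patientRecords <- function(patient, correct) {
  stopifnot(length(patient) == length(correct))
  agg <- stats::aggregate(list(nCorrect = as.integer(correct)),
                          by = list(patient = as.character(patient)), sum)
  agg$nImages <- as.integer(table(patient)[agg$patient])
  agg[, c("patient", "nImages", "nCorrect")]
}

#' Write an evaluation report to text and delimited files
#'
#' Emits a human-readable summary and, alongside it, a CSV of the confusion
#' matrix (labels as header row/column) and a CSV of per-class rows followed
#' by the weighted summary.
#'
#' @param report an \code{\linkS4class{EvaluationReport}}.
#' @param prefix path prefix; writes \code{<prefix>.txt},
#'   \code{<prefix>_confusion.csv} and \code{<prefix>_metrics.csv}.
#' @return the three paths, invisibly.
#' @export
writeReport <- function(report, prefix) {
  stopifnot(is(report, "EvaluationReport"))
  txt <- paste0(prefix, ".txt")
  sink(txt); show(report); sink()
  confCsv <- paste0(prefix, "_confusion.csv")
  utils::write.csv(report@confusion, confCsv)
  metCsv <- paste0(prefix, "_metrics.csv")
  pc <- report@perClass
  w <- report@weighted
  pc <- rbind(pc, data.frame(class = "weighted", support = sum(pc$support),
                             precision = w["precision"], recall = w["recall"],
                             f = w["f"]))
  utils::write.csv(pc, metCsv, row.names = FALSE)
  invisible(c(txt, confCsv, metCsv))
}

#' Repeated random-split trials of the full pipeline
#'
#' Runs the repeated-trials protocol: for each trial, a fresh seeded
#' stratified split of the images into training and test parts (using the
#' train and test components of the configured fractions), a full pipeline
#' fit on the training part and weighted metrics on the test part.  The
#' per-trial F-measures are the inputs to \code{\link{pairedTTest}} when two
#' pipelines are compared over the same trials.
#'
#' @param images list of grayscale matrices.
#' @param labels class label per image.
#' @param config a \code{\link{runConfig}}; supplies detector parameters,
#'   codebook size, kernel, number of trials and the master seed (trial
#'   seeds are derived substreams).
#' @param pyramid spatial-pyramid levels (1 = flat).
#' @param features optional precomputed list of
#'   \code{\linkS4class{SiftFeatures}} to reuse across trials.
#' @return data.frame with one row per trial: \code{trial}, \code{f},
#'   \code{precision}, \code{recall}, \code{accuracy}, plus the mean and sd
#'   of F as attributes \code{meanF} and \code{sdF}.
#' @export
repeatedTrials <- function(images, labels, config = runConfig(),
                           pyramid = 1L, features = NULL) {
  labels <- as.character(labels)
  if (is.null(features))
    features <- lapply(images, extractFeatures, params = config$sift)
  trainShare <- config$fractions[1] / (config$fractions[1] +
                                       config$fractions[3])
  rows <- lapply(seq_len(config$trials), function(t) {
    idx <- .withSeed(.deriveSeed(config$seed, paste0("trial-", t)), {
      unlist(lapply(split(seq_along(labels), labels), function(ix) {
        ntr <- min(max(1L, round(length(ix) * trainShare)),
                   length(ix) - 1L)
        sample(ix)[seq_len(ntr)]
      }), use.names = FALSE)
    })
    hold <- setdiff(seq_along(labels), idx)
    fit <- suppressWarnings(trainImageClassifier(
      NULL, labels[idx], params = config$sift,
      codebookSize = config$codebookSize, kernel = config$kernel,
      pyramid = pyramid,
      seed = .deriveSeed(config$seed, paste0("trial-fit-", t)),
      features = features[idx]))
    pred <- suppressWarnings(predictImages(fit, NULL,
                                           features = features[hold]))
    ok <- !is.na(pred$label)
    rep <- suppressWarnings(
      evaluatePredictions(labels[hold][ok], pred$label[ok],
                          classes = sort(unique(labels))))
    w <- weightedMetrics(rep)
    data.frame(trial = t, f = w[["f"]], precision = w[["precision"]],
               recall = w[["recall"]], accuracy = w[["accuracy"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "meanF") <- mean(out$f)
  attr(out, "sdF") <- stats::sd(out$f)
  out
}
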