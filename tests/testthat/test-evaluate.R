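test_that("perfect predictions give unit metrics and a diagonal confusion matrix", {
  rep <- evaluatePredictions(c("a", "b", "c", "a"), c("a", "b", "c", "a"))
  expect_true(all(perClassMetrics(rep)$precision == 1))
  expect_true(all(perClassMetrics(rep)$recall == 1))
  expect_equal(unname(weightedMetrics(rep)),
               c(1, 1, 1, 1))
  expect_equal(sum(confusionMatrix(rep)), 4)
  expect_equal(sum(diag(confusionMatrix(rep))), 4)
})

test_that("the two-class worked example matches hand-computed weighted metrics", {
  # confusion rows (2,0) / (1,1): class a P=2/3 R=1, class b P=1 R=1/2
  actual <- c("a", "a", "b", "b")
  predicted <- c("a", "a", "a", "b")
  rep <- evaluatePredictions(actual, predicted)
  w <- weightedMetrics(rep)
  expect_equal(unname(w["precision"]), 0.83333, tolerance = 1e-4)
  expect_equal(unname(w["recall"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(w["f"]), 0.73333, tolerance = 1e-4)
})

test_that("a never-predicted class gets precision 0 with a warning", {
  expect_warning(
    rep <- evaluatePredictions(c("a", "a", "b", "b"), c("a", "a", "a", "a")),
    "never predicted")
  pc <- perClassMetrics(rep)
  expect_equal(pc$precision[pc$class == "b"], 0)
  expect_error(evaluatePredictions(c("a", "b"), c("a", "z"),
                                   classes = c("a", "b")), "outside")
})

test_that("weighted metrics match a brute-force oracle on random label vectors", {
  set.seed(99)
  classes <- letters[1:5]
  for (i in 1:100) {
    n <- sample(20:60, 1)
    actual <- sample(classes, n, replace = TRUE)
    predicted <- sample(classes, n, replace = TRUE)
    # ensure every class appears as actual so supports are positive
    actual[1:5] <- classes
    rep <- suppressWarnings(
      evaluatePredictions(actual, predicted, classes = classes))
    oracle <- bruteForceMetrics(actual, predicted, classes)
    w <- weightedMetrics(rep)
    expect_equal(unname(w[c("precision", "recall", "f")]), unname(oracle),
                 tolerance = 1e-9)
    # support-weighted recall equals overall accuracy
    expect_equal(unname(w["recall"]), mean(actual == predicted),
                 tolerance = 1e-12)
  }
})

test_that("the paired t-test matches stats::t.test and flags degeneracy", {
  set.seed(3)
  a <- stats::runif(10, 0.7, 0.8)
  b <- a + 0.1 + stats::rnorm(10, 0, 1e-3)
  res <- pairedTTest(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_true(res$significant)        # constant +0.1 shift over 10 trials

  same <- pairedTTest(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$p, 1)
  expect_false(same$significant)
  expect_true(same$degenerate)

  shifted <- pairedTTest(c(0.5, 0.6), c(0.6, 0.7))
  expect_equal(shifted$p, 0)
  expect_true(shifted$significant)

  expect_error(pairedTTest(0.5, 0.6), "at least 2")
})

test_that("majority vote returns the plurality label and honours tie-breaks", {
  unanimous <- majorityVote(rep("ganglioneuroma", 10))
  expect_equal(unanimous$label, "ganglioneuroma")
  expect_equal(unanimous$count, 10)

  # 4 poorly-differentiated vs 6 differentiating: plurality wins
  mixed <- majorityVote(rep(c("poorly-differentiated", "differentiating"),
                            c(4, 6)))
  expect_equal(mixed$label, "differentiating")
  expect_equal(mixed$count, 6)
  expect_equal(unname(mixed$tally[["poorly-differentiated"]]), 4)

  # 5-5 tie broken by the larger summed decision score
  scores <- cbind(A = c(rep(1, 5), rep(0.2, 5)),
                  B = c(rep(0.5, 5), rep(0.6, 5)))
  tie <- suppressMessages(
    majorityVote(rep(c("A", "B"), each = 5), scores = scores))
  expect_equal(tie$label, "A")
  expect_equal(tie$count, 5)
  # ... and lexicographically without scores
  lex <- suppressMessages(majorityVote(rep(c("B", "A"), each = 5)))
  expect_equal(lex$label, "A")
})

test_that("recognition rate averages per-patient image accuracy", {
  one <- data.frame(patient = "p", nImages = 7, nCorrect = 7)
  expect_equal(recognitionRate(one), 1.0)

  two <- data.frame(patient = c("p1", "p2"), nImages = c(4, 2),
                    nCorrect = c(3, 1))
  expect_equal(recognitionRate(two), 0.625)      # (0.75 + 0.5) / 2

  # duplicating every patient leaves the mean unchanged
  expect_equal(recognitionRate(rbind(two, two)), 0.625)
  # ... and so does reordering
  expect_equal(recognitionRate(two[2:1, ]), 0.625)

  expect_error(recognitionRate(data.frame(patient = "p", nImages = 0,
                                          nCorrect = 0)), "NP >= 1")
  expect_error(recognitionRate(data.frame(patient = "p", nImages = 2,
                                          nCorrect = 3)), "Nrec")
})

test_that("patient records aggregate per-image correctness", {
  rec <- patientRecords(c("p1", "p1", "p1", "p2", "p2"),
                        c(TRUE, FALSE, TRUE, TRUE, TRUE))
  rec <- rec[order(rec$patient), ]
  expect_equal(rec$nImages, c(3L, 2L))
  expect_equal(rec$nCorrect, c(2L, 2L))
  expect_equal(recognitionRate(rec), (2 / 3 + 1) / 2)
})

test_that("recognition rate is bounded in [0, 1] on random records", {
  set.seed(8)
  for (i in 1:20) {
    np <- sample(1:10, 6, replace = TRUE)
    rec <- data.frame(patient = paste0("p", 1:6), nImages = np,
                      nCorrect = vapply(np, function(n) sample(0:n, 1),
                                        integer(1)))
    r <- recognitionRate(rec)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("reports are written as text plus delimited files", {
  rep <- evaluatePredictions(c("a", "a", "b", "b"), c("a", "a", "a", "b"))
  dir <- withr::local_tempdir()
  paths <- writeReport(rep, file.path(dir, "eval"))
  expect_true(all(file.exists(file.path(dir, c("eval.txt",
                                               "eval_confusion.csv",
                                               "eval_metrics.csv")))))
  conf <- utils::read.csv(file.path(dir, "eval_confusion.csv"),
                          row.names = 1)
  expect_equal(unname(as.matrix(conf)), unname(confusionMatrix(rep)))
  met <- utils::read.csv(file.path(dir, "eval_metrics.csv"))
  expect_equal(met$class, c("a", "b", "weighted"))
})

test_that("repeated trials produce per-trial weighted metrics with seeded splits", {
  specs <- defaultClassSpecs(jitter = FALSE)[c(1, 3)]
  imgs <- list(); labs <- c()
  for (ci in 1:2) for (i in 1:8) {
    imgs[[length(imgs) + 1]] <- renderImage(specs[[ci]],
                                            seed = 500 + 10 * ci + i,
                                            dim = c(96, 96))
    labs <- c(labs, specs[[ci]]@name)
  }
  feats <- lapply(imgs, extractFeatures)
  cfg <- runConfig(codebookSize = 12L,
                   kernel = kernelSpec("histogram_intersection"),
                   trials = 3L, seed = 2)
  tab <- repeatedTrials(imgs, labs, cfg, features = feats)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$f >= 0 & tab$f <= 1))
  expect_equal(attr(tab, "meanF"), mean(tab$f))
  # same config, same features: identical trials (seed-stream contract)
  tab2 <- repeatedTrials(imgs, labs, cfg, features = feats)
  expect_equal(tab, tab2, ignore_attr = FALSE)
  # per-trial F lists feed the paired comparison harness
  cmp <- pairedTTest(tab$f, pmax(tab$f - 0.1, 0), alpha = 0.05)
  expect_true(is.finite(cmp$p) || cmp$degenerate)
})
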