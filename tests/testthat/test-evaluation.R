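test_that("metrics follow the confusion-count formulas", {
  r <- computeMetrics(c(1, 0), c(0.9, 0.1))
  expect_equal(unname(perfMetrics(r)), c(1, 1, 1, 1, 1))
  r2 <- computeMetrics(c(1, 0), c(0.1, 0.9))
  expect_equal(unname(perfMetrics(r2)[c("acc", "auroc")]), c(0, 0))
  r3 <- computeMetrics(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))
  expect_equal(unname(perfMetrics(r3)["auroc"]), 0.75)
  expect_error(computeMetrics(c(1, 0), 0.5), "length")
  expect_error(computeMetrics(integer(0), numeric(0)), "empty")
})

test_that("zero denominators are reported as flagged zeros", {
  r <- computeMetrics(c(1, 1, 0), c(0.2, 0.3, 0.1))   # nothing predicted 1
  expect_equal(unname(perfMetrics(r)[c("pre", "f1")]), c(0, 0))
  expect_true(zeroDenomFlags(r)["pre"])
  expect_false(zeroDenomFlags(r)["rec"])
  r2 <- computeMetrics(c(0, 0), c(0.1, 0.9))          # one-class input
  expect_true(is.na(perfMetrics(r2)["auroc"]))
  expect_true(zeroDenomFlags(r2)["auroc"])
})

test_that("stored metrics are self-consistent with stored counts", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    labels <- rbinom(n, 1, 0.5)
    scores <- round(runif(n), 2)             # rounding forces ties
    r <- computeMetrics(labels, scores)
    ct <- confusionCounts(r)
    m <- perfMetrics(r)
    expect_identical(sum(ct), as.integer(n))
    expect_equal(unname(m["acc"]),
                 unname((ct["TP"] + ct["TN"]) / sum(ct)))
    if (ct["TP"] + ct["FP"] > 0)
      expect_equal(unname(m["pre"]), unname(ct["TP"] / (ct["TP"] + ct["FP"])))
    if (ct["TP"] + ct["FN"] > 0)
      expect_equal(unname(m["rec"]), unname(ct["TP"] / (ct["TP"] + ct["FN"])))
    if (m["pre"] + m["rec"] > 0)
      expect_equal(unname(m["f1"]),
                   unname(2 * m["pre"] * m["rec"] / (m["pre"] + m["rec"])))
    if (length(unique(labels)) == 2)
      expect_equal(unname(m["auroc"]), oracleAuroc(labels, scores))
  }
})

test_that("AUROC has the rank-statistic invariances", {
  set.seed(12)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- runif(30)
  a <- perfMetrics(computeMetrics(labels, scores))["auroc"]
  mono <- perfMetrics(computeMetrics(labels, scores^3))["auroc"]
  expect_equal(unname(a), unname(mono))   # strictly monotone transform
  flip <- perfMetrics(computeMetrics(labels, 1 - scores))["auroc"]
  expect_equal(unname(a + flip), 1)       # no ties in runif scores
  skip_if_not_installed("pROC")
  for (i in 1:10) {
    l <- rbinom(20, 1, 0.5); l[1:2] <- c(0, 1)
    s <- round(runif(20), 1)
    mine <- perfMetrics(computeMetrics(l, s))["auroc"]
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(unname(mine), ref)
  }
})

test_that("pooled LOOCV is deterministic and aces separable data", {
  ds <- makeSeparableSet(5)
  r <- loocv(ds, encoderParams("kmer", k = 1),
             modelSpec("single_tree", maxDepth = 3), seed = 7)
  expect_equal(unname(perfMetrics(r)["acc"]), 1)
  r2 <- loocv(ds, encoderParams("kmer", k = 1),
              modelSpec("single_tree", maxDepth = 3), seed = 7)
  expect_identical(perfMetrics(r), perfMetrics(r2))
  expect_identical(r@protocol$protocol, "loocv")
})

test_that("LOOCV rejects degenerate class composition", {
  seqs <- Biostrings::RNAStringSet(c(a = "ACGUAC", b = "GGCCAA",
                                     c = "AUGCAU"))
  ds <- labeledRnaSet(seqs, c(1L, 0L, 0L))
  expect_error(loocv(ds, encoderParams("kmer", k = 1)), "at least 2")
})

test_that("repeated stratified k-fold averages per-rep pooled reports", {
  ds <- makeSeparableSet(6)
  enc <- encoderParams("kmer", k = 1)
  spec <- modelSpec("single_tree", maxDepth = 3)
  a <- repeatedKfold(ds, enc, spec, folds = 3, reps = 2, seed = 5)
  b <- repeatedKfold(ds, enc, spec, folds = 3, reps = 2, seed = 5)
  expect_identical(a$mean, b$mean)
  expect_equal(unname(a$mean["acc"]), 1)
  perRep <- vapply(a$reports, function(r) perfMetrics(r)["auroc"],
                   numeric(1))
  expect_gte(a$mean["auroc"], min(perRep))
  expect_lte(a$mean["auroc"], max(perRep))
  expect_error(repeatedKfold(makeSeparableSet(2), enc, spec, folds = 5),
               "5 folds")
})

test_that("sequential scan fixes parameters in order with first-win ties", {
  grid <- gridSpec(list(a = 1:5, b = 1:4), defaults = list(b = 1),
                   objective = "acc")
  # additively separable objective with a planted argmax at (3, 2)
  obj <- function(p) -(p$a - 3)^2 - (p$b - 2)^2
  res <- sequentialGridSearch(grid, obj)
  expect_identical(res$best$a, 3L)
  expect_identical(res$best$b, 2L)
  expect_identical(nrow(res$trace), 9L)          # 5 + 4, coordinate-wise
  expect_identical(res$bestObjective, obj(list(a = 3, b = 2)))
  expect_true(any(res$trace$param == "a" & res$trace$value == "3" &
                  res$trace$objective == -1))
  # constant objective keeps the first-listed values
  resC <- sequentialGridSearch(grid, function(p) 0.5)
  expect_identical(resC$best$a, 1L)
  expect_identical(resC$best$b, 1L)
  # a one-parameter grid is an exhaustive scan of that parameter
  res1 <- sequentialGridSearch(gridSpec(list(a = 1:5), objective = "acc"),
                               function(p) -abs(p$a - 4))
  expect_identical(res1$best$a, 4L)
  expect_identical(nrow(res1$trace), 5L)
  # failures abort naming the cell
  expect_error(
    sequentialGridSearch(grid, function(p)
      if (p$a == 2) stop("boom") else 0),
    "a=2.*boom")
})

test_that("preset grids reproduce the calibration ranges", {
  expect_identical(presetGrid("kmer")@params$k, 1:6)
  xg <- presetGrid("xgb")
  expect_identical(xg@params$nTrees, seq(50L, 500L, 10L))
  expect_equal(xg@params$learningRate, seq(0.1, 0.5, 0.02))
  expect_identical(xg@params$maxDepth, 3:10)
  expect_equal(xg@params$regLambda, seq(0, 2, 0.1))
  expect_identical(xg@objective, "auroc")
  mm <- presetGrid("mismatch")
  expect_identical(mm@params$k, 1:6)
  expect_identical(mm@params$m(list(k = 4L)), 0:3)   # adaptive range
  ct <- presetGrid("cart", n = 16)
  expect_identical(ct@params$maxFeatures, 3:16)
  expect_identical(ct@params$splitter, c("best", "random"))
  expect_error(presetGrid("cart"), "dimension")
  sub <- presetGrid("subsequence")
  expect_identical(sub@params$k, 2:4)
  expect_equal(sub@params$delta, seq(0.1, 0.9, 0.1))
  ps <- presetGrid("psedsspc")
  expect_identical(ps@params$d, 1:10)
  expect_identical(ps@params$lambda, 1:20)
})

test_that("the LOOCV objective drives a small end-to-end calibration", {
  ds <- makeSeparableSet(4, len = 20)
  obj <- loocvObjective(ds, "kmer", kind = "single_tree", metric = "acc",
                        seed = 3)
  res <- sequentialGridSearch(gridSpec(list(k = 1:2), objective = "acc"),
                              obj)
  expect_identical(nrow(res$trace), 2L)
  expect_equal(res$bestObjective, 1)   # separable at any k
  expect_identical(res$best$k, 1L)     # tie broken toward the simpler k
})
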