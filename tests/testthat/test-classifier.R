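# small helper: separable one-feature data
.sep1d <- function(n = 10) {
  X <- matrix(c(seq(0, 0.4, length.out = n / 2),
                seq(0.6, 1, length.out = n / 2)), ncol = 1)
  colnames(X) <- "f1"
  rownames(X) <- sprintf("s%02d", seq_len(n))
  list(X = X, y = rep(c(0L, 1L), each = n / 2))
}

test_that("Gini impurity follows its closed form", {
  expect_identical(giniIndex(c(1, 0)), 0)
  expect_identical(giniIndex(c(0.5, 0.5)), 0.5)
  expect_identical(giniIndex(rep(0.25, 4)), 0.75)
  expect_error(giniIndex(c(0.5, 0.6)), "sum to 1")
  expect_error(giniIndex(c(-0.1, 1.1)), "non-negative")
  # maximized at uniform, zero exactly at pure nodes
  set.seed(1)
  for (k in 2:5) {
    u <- giniIndex(rep(1 / k, k))
    for (i in 1:5) {
      p <- runif(k); p <- p / sum(p)
      expect_lte(giniIndex(p), u + 1e-12)
    }
    e <- rep(0, k); e[1] <- 1
    expect_identical(giniIndex(e), 0)
  }
})

test_that("branch purity is the size-weighted mean of subset Gini", {
  expect_identical(branchPurity(c(3, 7), list(c(1, 0), c(0, 1))), 0)
  expect_equal(branchPurity(c(2, 2), list(c(1, 0), c(0.5, 0.5))), 0.25)
  p <- c(0.3, 0.7)
  expect_identical(branchPurity(5, list(p)), giniIndex(p))
  expect_error(branchPurity(integer(0), list()), "non-empty")
})

test_that("single trees separate separable data and honor the depth cap", {
  d <- .sep1d()
  fit <- trainTree(d$X, d$y, maxDepth = 3)
  expect_identical(as.integer(predictProba(fit, d$X) >= 0.5), d$y)
  set.seed(3)
  X <- matrix(runif(600), 100, 6)
  y <- as.integer(runif(100) > 0.5)
  for (splitter in c("best", "random")) {
    fit <- trainTree(X, y, splitter = splitter, maxDepth = 3,
                     maxFeatures = 3, seed = 9)
    expect_lte(essMiR:::.treeDepth(fit@fit$tree), 3L)
    again <- trainTree(X, y, splitter = splitter, maxDepth = 3,
                       maxFeatures = 3, seed = 9)
    expect_identical(predictProba(fit, X), predictProba(again, X))
  }
  expect_error(trainTree(X, rep(1L, 100)), "single class")
  expect_error(trainTree(X, y, maxFeatures = 7), "maxFeatures")
})

test_that("a deep unpruned tree reaches hard 0/1 leaves on training data", {
  set.seed(4)
  X <- matrix(runif(200), 50, 4)
  y <- as.integer(X[, 1] + X[, 2] > 1)
  fit <- trainTree(X, y, maxDepth = 25)
  expect_true(all(predictProba(fit, X) %in% c(0, 1)))
})

test_that("best-split trees agree with rpart on clean data", {
  skip_if_not_installed("rpart")
  set.seed(5)
  X <- matrix(runif(300), 100, 3)
  colnames(X) <- paste0("f", 1:3)
  y <- as.integer(X[, 2] > 0.5)
  mine <- predictProba(trainTree(X, y, maxDepth = 4), X)
  rp <- rpart::rpart(y ~ ., data.frame(X, y = y), method = "class",
                     parms = list(split = "gini"),
                     control = rpart::rpart.control(maxdepth = 4,
                                                    cp = 0, minsplit = 2))
  theirs <- stats::predict(rp, data.frame(X))[, "1"]
  expect_gte(mean((mine >= 0.5) == (theirs >= 0.5)), 0.99)
})

test_that("the boosted ensemble fits, regularizes, and is deterministic", {
  set.seed(6)
  X <- matrix(rnorm(400), 100, 4)
  y <- as.integer(X[, 1] + 0.1 * rnorm(100) > 0)
  fit <- trainBoosted(X, y, nTrees = 50, seed = 2)
  s <- predictProba(fit, X)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(perfMetrics(computeMetrics(y, s))["auroc"]), 1)
  again <- trainBoosted(X, y, nTrees = 50, seed = 2)
  expect_identical(predictProba(again, X), s)
  # heavy L2 with few trees shrinks scores toward the base rate
  loose <- predictProba(trainBoosted(X, y, nTrees = 5, regLambda = 0,
                                     seed = 2), X)
  tight <- predictProba(trainBoosted(X, y, nTrees = 5, regLambda = 500,
                                     seed = 2), X)
  expect_lt(stats::var(tight), stats::var(loose))
  expect_error(trainBoosted(X, rep(0L, 100)), "single class")
})

test_that("one unshrunk boosting round behaves like a single tree", {
  d <- .sep1d(20)
  b <- predictProba(trainBoosted(d$X, d$y, nTrees = 1, learningRate = 1,
                                 maxDepth = 6, regLambda = 0), d$X)
  t1 <- predictProba(trainTree(d$X, d$y, maxDepth = 6), d$X)
  expect_identical(as.integer(b >= 0.5), as.integer(t1 >= 0.5))
})

test_that("prediction enforces feature provenance", {
  seqs <- c(a = "ACGUACGUAC", b = "GGGCCCAAUU", c = "AAAUUUGGGC",
            d = "CACACAGUGU")
  fm2 <- batchEncode(seqs, encoderParams("kmer", k = 2))
  fm3 <- batchEncode(seqs, encoderParams("kmer", k = 3))
  fit <- trainBoosted(fm2, c(1L, 1L, 0L, 0L), nTrees = 5)
  expect_error(predictProba(fit, fm3), "kmer\\(k=3\\)")
  expect_error(predictProba(fit, fm3), "kmer\\(k=2\\)")
  expect_silent(predictProba(fit, fm2))
})

test_that("model artifacts round-trip bit-identical predictions", {
  seqs <- c(a = "ACGUACGUAC", b = "GGGCCCAAUU", c = "AAAUUUGGGC",
            d = "CACACAGUGU")
  fm <- batchEncode(seqs, encoderParams("kmer", k = 2))
  y <- c(1L, 1L, 0L, 0L)
  for (fit in list(trainBoosted(fm, y, nTrees = 10, seed = 5),
                   trainTree(fm, y, seed = 5))) {
    path <- withr::local_tempfile(fileext = ".rds")
    saveModel(fit, path)
    back <- loadModel(path)
    expect_identical(predictProba(back, fm), predictProba(fit, fm))
    expect_identical(modelParams(back), modelParams(fit))
    expect_identical(back@seed, fit@seed)
  }
  expect_error(loadModel(withr::local_tempfile()), "not found")
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(schema = "something-else"), junk)
  expect_error(loadModel(junk), "incompatible")
})

test_that("tampered provenance is caught at prediction time", {
  seqs <- c(a = "ACGUACGUAC", b = "GGGCCCAAUU", c = "AAAUUUGGGC",
            d = "CACACAGUGU")
  fm <- batchEncode(seqs, encoderParams("kmer", k = 2))
  fit <- trainBoosted(fm, c(1L, 1L, 0L, 0L), nTrees = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(fit, path)
  bundle <- readRDS(path)
  bundle$encoder$k <- 3L
  saveRDS(bundle, path)
  expect_error(predictProba(loadModel(path), fm), "provenance mismatch")
})
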