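## Gini-criterion classification trees and the gradient-boosted ensemble.
## The single-tree stage is grown in-package so that the calibration grid's
## splitter randomness (S) and per-split feature subsampling (M) are honored
## exactly; the boosted stage delegates to xgboost (binary:logistic,
## single-threaded for determinism).

MODEL_SCHEMA <- "essMiR-model-1"

#' Gini impurity of a node
#'
#' `G = sum p_i (1 - p_i) = 1 - sum p_i^2` over the class proportions of
#' a node; 0 for a pure node, maximal (`1 - 1/k`) at the uniform
#' distribution over k classes.
#'
#' @param proportions non-negative class proportions summing to 1.
#' @return the impurity, in \[0, 1 - 1/k\].
#' @examples
#' giniIndex(c(0.5, 0.5))  # 0.5
#' @export
giniIndex <- function(proportions) {
  if (!is.numeric(proportions) || any(proportions < 0))
    stop("proportions must be non-negative", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", format(sum(proportions)), ")",
         call. = FALSE)
  1 - sum(proportions^2)
}

#' Size-weighted impurity of a candidate branching
#'
#' `I = sum_j (|D_j| / |D|) G(D_j)` over the subsets a split induces;
#' the quantity a tree split minimizes.
#'
#' @param sizes positive subset sizes.
#' @param proportions list of per-subset class-proportion vectors.
#' @return the weighted mean Gini impurity.
#' @examples
#' branchPurity(c(2, 2), list(c(1, 0), c(0.5, 0.5)))  # 0.25
#' @export
branchPurity <- function(sizes, proportions) {
  if (length(sizes) == 0 || any(sizes <= 0))
    stop("every subset must be non-empty", call. = FALSE)
  if (length(proportions) != length(sizes))
    stop("one proportion vector per subset is required", call. = FALSE)
  g <- vapply(proportions, giniIndex, numeric(1))
  sum(sizes * g) / sum(sizes)
}

## ---- in-package CART ------------------------------------------------------

## best axis-aligned split of y (0/1) on feature x; returns NULL when x is
## constant. Binary Gini 2p(1-p) vectorized over the n-1 ordered cut points.
.bestSplit <- function(x, y) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(ys)
  cuts <- which(xs[-n] < xs[-1])
  if (!length(cuts)) return(NULL)
  cumPos <- cumsum(ys)
  nl <- cuts
  nr <- n - nl
  pl <- cumPos[cuts] / nl
  pr <- (cumPos[n] - cumPos[cuts]) / nr
  imp <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / n
  bestI <- which.min(imp)                     # ties: first (lowest) cut wins
  list(threshold = (xs[cuts[bestI]] + xs[cuts[bestI] + 1L]) / 2,
       impurity = imp[bestI])
}

## impurity of splitting at a fixed threshold
.splitImpurity <- function(x, y, thr) {
  left <- x <= thr
  nl <- sum(left); nr <- length(y) - nl
  if (nl == 0L || nr == 0L) return(NULL)
  pl <- mean(y[left]); pr <- mean(y[!left])
  (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / length(y)
}

.growTree <- function(X, y, depth, maxDepth, maxFeatures, splitter) {
  n <- length(y)
  prob <- mean(y)
  leaf <- list(leaf = TRUE, prob = prob, n = n)
  if (depth >= maxDepth || n < 2L || prob == 0 || prob == 1) return(leaf)
  p <- ncol(X)
  feats <- if (maxFeatures < p) sample.int(p, maxFeatures) else seq_len(p)
  nodeGini <- 2 * prob * (1 - prob)
  best <- NULL
  for (f in feats) {
    cand <- if (splitter == "best") {
      .bestSplit(X[, f], y)
    } else {
      rng <- range(X[, f])
      if (rng[1] == rng[2]) NULL else {
        thr <- stats::runif(1, rng[1], rng[2])
        imp <- .splitImpurity(X[, f], y, thr)
        if (is.null(imp)) NULL else list(threshold = thr, impurity = imp)
      }
    }
    if (!is.null(cand) &&
        (is.null(best) || cand$impurity < best$impurity)) {
      best <- cand; best$feature <- f
    }
  }
  if (is.null(best) || best$impurity >= nodeGini - 1e-12) return(leaf)
  left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       n = n,
       left = .growTree(X[left, , drop = FALSE], y[left],
                        depth + 1L, maxDepth, maxFeatures, splitter),
       right = .growTree(X[!left, , drop = FALSE], y[!left],
                         depth + 1L, maxDepth, maxFeatures, splitter))
}

.treeDepth <- function(node) {
  if (node$leaf) 0L
  else 1L + max(.treeDepth(node$left), .treeDepth(node$right))
}

.predictTreeRow <- function(node, xrow) {
  while (!node$leaf)
    node <- if (xrow[node$feature] <= node$threshold) node$left
            else node$right
  node$prob
}

.asMatrix <- function(features) {
  if (is(features, "FeatureMatrix")) featureValues(features)
  else as.matrix(features)
}

.checkTrainingData <- function(X, y) {
  if (nrow(X) != length(y))
    stop("feature rows and labels must align", call. = FALSE)
  if (nrow(X) < 2L)
    stop("at least 2 training samples are required", call. = FALSE)
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; both classes are required",
         call. = FALSE)
}

#' Train a single Gini-criterion classification tree
#'
#' Grows a binary CART-style classification tree whose splits minimize the
#' size-weighted Gini impurity ([branchPurity()]). `splitter = "best"`
#' evaluates every cut point of each candidate feature; `"random"` draws
#' one uniform threshold per candidate feature and keeps the best.
#' `maxFeatures` candidate features are drawn uniformly at each split.
#' Training is a pure function of (features, labels, parameters, seed).
#'
#' @param features a [FeatureMatrix-class] (or plain numeric matrix).
#' @param labels 0/1 labels, 1 = essential; both classes must be present.
#' @param splitter `"best"` or `"random"`.
#' @param maxDepth maximum tree depth (root = depth 0).
#' @param maxFeatures candidate features per split; default all.
#' @param seed integer seed.
#' @return a [TrainedModel-class] of kind `"single_tree"`.
#' @export
trainTree <- function(features, labels, splitter = c("best", "random"),
                      maxDepth = 6L, maxFeatures = NULL, seed = 1L) {
  splitter <- match.arg(splitter)
  X <- .asMatrix(features)
  y <- as.integer(labels)
  .checkTrainingData(X, y)
  if (maxDepth < 1L) stop("maxDepth must be >= 1", call. = FALSE)
  if (is.null(maxFeatures)) maxFeatures <- ncol(X)
  if (maxFeatures < 1L || maxFeatures > ncol(X))
    stop("maxFeatures must lie in [1, ", ncol(X), "], got ", maxFeatures,
         call. = FALSE)
  tree <- .withSeed(seed,
    .growTree(X, y, 0L, as.integer(maxDepth),
              as.integer(maxFeatures), splitter))
  ep <- if (is(features, "FeatureMatrix")) featureParams(features) else NULL
  new("TrainedModel", kind = "single_tree",
      modelParams = list(splitter = splitter,
                         maxDepth = as.integer(maxDepth),
                         maxFeatures = as.integer(maxFeatures)),
      encoderParams = ep, seed = as.integer(seed),
      fit = list(tree = tree, nFeatures = ncol(X)),
      engine = paste0("essMiR-cart ",
                      as.character(utils::packageVersion("essMiR"))),
      schemaVersion = MODEL_SCHEMA)
}

#' Train the gradient-boosted tree ensemble
#'
#' Fits `nTrees` depth-capped regression trees by gradient boosting with a
#' logistic objective, shrinkage `learningRate` and L2 leaf regularization
#' `regLambda`, via the xgboost library (single-threaded, deterministic
#' under the seed).
#'
#' @param features a [FeatureMatrix-class] (or numeric matrix).
#' @param labels 0/1 labels, 1 = essential.
#' @param nTrees number of boosting rounds (calibration grid 50..500).
#' @param learningRate shrinkage (grid 0.1..0.5).
#' @param maxDepth per-tree depth cap (grid 3..10).
#' @param regLambda L2 regularization (grid 0..2).
#' @param seed integer seed.
#' @return a [TrainedModel-class] of kind `"boosted"`.
#' @export
trainBoosted <- function(features, labels, nTrees = 100L,
                         learningRate = 0.3, maxDepth = 6L,
                         regLambda = 1, seed = 1L) {
  X <- .asMatrix(features)
  y <- as.integer(labels)
  .checkTrainingData(X, y)
  if (nTrees < 1L) stop("nTrees must be >= 1", call. = FALSE)
  if (learningRate <= 0) stop("learningRate must be > 0", call. = FALSE)
  if (regLambda < 0) stop("regLambda must be >= 0", call. = FALSE)
  booster <- .withSeed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = learningRate,
                  max_depth = as.integer(maxDepth),
                  lambda = regLambda,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = as.integer(nTrees), verbose = 0))
  ep <- if (is(features, "FeatureMatrix")) featureParams(features) else NULL
  new("TrainedModel", kind = "boosted",
      modelParams = list(nTrees = as.integer(nTrees),
                         learningRate = learningRate,
                         maxDepth = as.integer(maxDepth),
                         regLambda = regLambda),
      encoderParams = ep, seed = as.integer(seed),
      fit = list(booster = booster, nFeatures = ncol(X)),
      engine = paste0("xgboost ",
                      as.character(utils::packageVersion("xgboost"))),
      schemaVersion = MODEL_SCHEMA)
}

.paramsLabel <- function(p) {
  vals <- c(k = p@k, m = p@m, delta = p@delta,
            d = p@d, lambda = p@lambda, w = p@w)
  vals <- vals[!is.na(vals)]
  paste0(p@scheme,
         if (length(vals))
           paste0("(", paste(names(vals), vals, sep = "=", collapse = ", "),
                  ")") else "")
}

.sameParams <- function(a, b) {
  identical(a@scheme, b@scheme) &&
    identical(a@k, b@k) && identical(a@m, b@m) &&
    identical(a@delta, b@delta) && identical(a@d, b@d) &&
    identical(a@lambda, b@lambda) && identical(a@w, b@w)
}

#' Predict essentiality probabilities
#'
#' Scores each row of a feature matrix with a trained model. The matrix's
#' encoder provenance must match the provenance the model was trained
#' with (same scheme, same parameters, same dimension); a mismatch is an
#' error naming both. Thresholding the scores at 0.5 gives the hard
#' predicted labels.
#'
#' @param model a [TrainedModel-class].
#' @param features a [FeatureMatrix-class].
#' @return named numeric scores in \[0, 1\], one per row.
#' @export
predictProba <- function(model, features) {
  stopifnot(is(model, "TrainedModel"))
  if (is(features, "FeatureMatrix") && !is.null(model@encoderParams)) {
    if (!.sameParams(model@encoderParams, featureParams(features)))
      stop("feature provenance mismatch: model was trained on ",
           .paramsLabel(model@encoderParams), " but the matrix is ",
           .paramsLabel(featureParams(features)), call. = FALSE)
  }
  X <- .asMatrix(features)
  if (ncol(X) != model@fit$nFeatures)
    stop("feature dimension mismatch: model expects ",
         model@fit$nFeatures, " features, matrix has ", ncol(X),
         call. = FALSE)
  scores <- if (model@kind == "boosted") {
    as.numeric(stats::predict(model@fit$booster, xgboost::xgb.DMatrix(X)))
  } else {
    apply(X, 1, function(r) .predictTreeRow(model@fit$tree, r))
  }
  stats::setNames(pmin(pmax(scores, 0), 1), rownames(X))
}

#' Persist / restore a trained model
#'
#' The artifact is a single-file bundle embedding the fitted state, the
#' model and encoder provenance, the seed, and the schema and library
#' versions. `loadModel()` refuses artifacts with an unknown schema
#' version; predictions after a round trip are bit-identical.
#'
#' @param model a [TrainedModel-class].
#' @param path artifact path.
#' @return `saveModel`: invisibly, `path`; `loadModel`: the restored
#'   [TrainedModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  fit <- model@fit
  if (model@kind == "boosted")
    fit$booster <- xgboost::xgb.save.raw(fit$booster)
  bundle <- list(schema = MODEL_SCHEMA,
                 kind = model@kind,
                 modelParams = model@modelParams,
                 encoder = if (is.null(model@encoderParams)) NULL else
                   list(scheme = model@encoderParams@scheme,
                        k = model@encoderParams@k,
                        m = model@encoderParams@m,
                        delta = model@encoderParams@delta,
                        d = model@encoderParams@d,
                        lambda = model@encoderParams@lambda,
                        w = model@encoderParams@w),
                 seed = model@seed, engine = model@engine, fit = fit,
                 packageVersion =
                   as.character(utils::packageVersion("essMiR")))
  tmp <- paste0(path, ".tmp")
  saveRDS(bundle, tmp)
  if (!file.rename(tmp, path))
    stop("cannot write model to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path))
    stop("model file not found: ", path, call. = FALSE)
  bundle <- readRDS(path)
  if (!is.list(bundle) || !identical(bundle$schema, MODEL_SCHEMA))
    stop("incompatible model artifact (expected schema '", MODEL_SCHEMA,
         "', found '", if (is.list(bundle)) bundle$schema else "?", "')",
         call. = FALSE)
  fit <- bundle$fit
  if (bundle$kind == "boosted")
    fit$booster <- xgboost::xgb.load.raw(fit$booster)
  e <- bundle$encoder
  ep <- if (is.null(e)) NULL else
    encoderParams(e$scheme, k = e$k, m = e$m, delta = e$delta,
                  d = e$d, lambda = e$lambda, w = e$w)
  new("TrainedModel", kind = bundle$kind, modelParams = bundle$modelParams,
      encoderParams = ep,
      seed = as.integer(bundle$seed), fit = fit, engine = bundle$engine,
      schemaVersion = bundle$schema)
}
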