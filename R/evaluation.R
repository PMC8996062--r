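## Performance metrics, the two cross-validation protocols (pooled LOOCV and
## repeated stratified 5-fold), and the sequential (coordinate-wise)
## grid-search calibration.

#' Compute the five performance statistics from labels and scores
#'
#' Confusion counts come from thresholding the scores at `cutoff`
#' (score >= cutoff predicts essential). Accuracy, precision, recall and
#' F1 follow the usual confusion-count formulas; AUROC is the rank
#' statistic (probability a random positive outscores a random negative,
#' ties counted 1/2). A zero denominator makes the affected metric 0 and
#' sets its flag; AUROC is `NA` (flagged) when only one class is present.
#'
#' @param labels 0/1 truth, 1 = essential.
#' @param scores numeric scores in \[0, 1\].
#' @param cutoff threshold for hard labels.
#' @param protocol list describing how the scores were produced.
#' @return a [MetricsReport-class].
#' @examples
#' r <- computeMetrics(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))
#' perfMetrics(r)["auroc"]  # 0.75
#' @export
computeMetrics <- function(labels, scores, cutoff = 0.5,
                           protocol = list(protocol = "scores")) {
  labels <- as.integer(labels)
  if (length(labels) == 0)
    stop("empty input", call. = FALSE)
  if (length(labels) != length(scores))
    stop("labels and scores must have the same length", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  pred <- as.integer(scores >= cutoff)
  counts <- c(TP = sum(pred == 1L & labels == 1L),
              TN = sum(pred == 0L & labels == 0L),
              FP = sum(pred == 1L & labels == 0L),
              FN = sum(pred == 0L & labels == 1L))
  flags <- c(pre = FALSE, rec = FALSE, f1 = FALSE, auroc = FALSE)
  acc <- (counts["TP"] + counts["TN"]) / length(labels)
  pre <- if (counts["TP"] + counts["FP"] == 0L) {
    flags["pre"] <- TRUE; 0
  } else counts["TP"] / (counts["TP"] + counts["FP"])
  rec <- if (counts["TP"] + counts["FN"] == 0L) {
    flags["rec"] <- TRUE; 0
  } else counts["TP"] / (counts["TP"] + counts["FN"])
  f1 <- if (pre + rec == 0) {
    flags["f1"] <- TRUE; 0
  } else 2 * pre * rec / (pre + rec)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  auroc <- if (nPos == 0L || nNeg == 0L) {
    flags["auroc"] <- TRUE; NA_real_
  } else {
    r <- rank(scores)  # average ranks => tied pairs contribute 1/2
    (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  }
  new("MetricsReport",
      counts = stats::setNames(as.integer(counts), names(counts)),
      metrics = c(acc = unname(acc), pre = unname(pre), rec = unname(rec),
                  f1 = unname(f1), auroc = unname(auroc)),
      flags = flags, protocol = protocol, cutoff = cutoff)
}

#' Describe a model for the cross-validation protocols
#'
#' @param kind `"boosted"` or `"single_tree"`.
#' @param ... hyper-parameters forwarded to [trainBoosted()] /
#'   [trainTree()] (e.g. `nTrees`, `learningRate`, `maxDepth`,
#'   `regLambda`; `splitter`, `maxFeatures`).
#' @return a model-spec list consumed by [loocv()], [repeatedKfold()].
#' @export
modelSpec <- function(kind = c("boosted", "single_tree"), ...) {
  kind <- match.arg(kind)
  list(kind = kind, params = list(...))
}

.trainFromSpec <- function(X, y, spec, seed) {
  fn <- if (spec$kind == "boosted") trainBoosted else trainTree
  do.call(fn, c(list(features = X, labels = y, seed = seed), spec$params))
}

.encodeDataset <- function(dataset, encoder, structures, energyTable) {
  stopifnot(is(dataset, "LabeledRnaSet"))
  batchEncode(dataset, encoder, structures = structures,
              energyTable = energyTable)
}

#' Leave-one-out cross-validation with pooled scoring
#'
#' Each sequence is scored by a model trained on the other n - 1; the n
#' held-out scores are pooled into a single [MetricsReport-class]
#' (per-fold ROC is undefined for singleton folds). Features are encoded
#' once up front — the encoders are per-sequence, so this leaks nothing.
#'
#' @param dataset a [LabeledRnaSet-class] with at least 2 members of each
#'   class.
#' @param encoder an [EncoderParams-class].
#' @param spec a [modelSpec()].
#' @param seed integer seed used for every fold's training.
#' @param structures,energyTable forwarded to [batchEncode()].
#' @return a [MetricsReport-class] over the pooled held-out scores.
#' @export
loocv <- function(dataset, encoder, spec = modelSpec("boosted"), seed = 1L,
                  structures = NULL, energyTable = defaultEnergyTable()) {
  y <- essLabels(dataset)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("LOOCV needs at least 2 members of each class (got ",
         sum(y == 1L), " essential, ", sum(y == 0L), " non-essential)",
         call. = FALSE)
  fm <- .encodeDataset(dataset, encoder, structures, energyTable)
  X <- featureValues(fm)
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit <- .trainFromSpec(X[-i, , drop = FALSE], y[-i], spec, seed)
    scores[i] <- predictProba(fit, X[i, , drop = FALSE])
  }
  computeMetrics(y, scores,
                 protocol = list(protocol = "loocv", n = n,
                                 seed = as.integer(seed),
                                 model = spec$kind,
                                 scheme = encoder@scheme))
}

#' Repeated stratified k-fold cross-validation
#'
#' Folds are stratified by class; repetition r derives its fold shuffle
#' and training seed from `seed + r`. Within a repetition all held-out
#' scores are pooled into one report; the five statistics are then
#' averaged arithmetically across repetitions.
#'
#' @param dataset a [LabeledRnaSet-class]; each class needs at least
#'   `folds` members.
#' @param encoder an [EncoderParams-class].
#' @param spec a [modelSpec()].
#' @param folds number of folds (default 5).
#' @param reps number of repetitions (default 50).
#' @param seed base integer seed.
#' @param structures,energyTable forwarded to [batchEncode()].
#' @return list with `mean` (named numeric: averaged acc/pre/rec/f1/auroc),
#'   `reports` (per-rep [MetricsReport-class] list) and `protocol`.
#' @export
repeatedKfold <- function(dataset, encoder, spec = modelSpec("boosted"),
                          folds = 5L, reps = 50L, seed = 1L,
                          structures = NULL,
                          energyTable = defaultEnergyTable()) {
  y <- essLabels(dataset)
  n <- length(y)
  if (n < folds)
    stop("cannot make ", folds, " folds from ", n, " samples",
         call. = FALSE)
  if (sum(y == 1L) < folds || sum(y == 0L) < folds)
    stop("stratified ", folds, "-fold CV needs at least ", folds,
         " members of each class (got ", sum(y == 1L), " essential, ",
         sum(y == 0L), " non-essential)", call. = FALSE)
  fm <- .encodeDataset(dataset, encoder, structures, energyTable)
  X <- featureValues(fm)
  reports <- vector("list", reps)
  for (r in seq_len(reps)) {
    repSeed <- as.integer(seed) + r
    fold <- .withSeed(repSeed, {
      f <- integer(n)
      for (cls in c(0L, 1L)) {
        idx <- sample(which(y == cls))
        f[idx] <- rep_len(seq_len(folds), length(idx))
      }
      f
    })
    scores <- numeric(n)
    for (f in seq_len(folds)) {
      test <- fold == f
      fit <- .trainFromSpec(X[!test, , drop = FALSE], y[!test], spec,
                            repSeed)
      scores[test] <- predictProba(fit, X[test, , drop = FALSE])
    }
    reports[[r]] <- computeMetrics(
      y, scores, protocol = list(protocol = "kfold", folds = folds,
                                 rep = r, seed = repSeed))
  }
  metricMat <- do.call(rbind, lapply(reports, perfMetrics))
  list(mean = colMeans(metricMat),
       reports = reports,
       protocol = list(protocol = "kfold", folds = as.integer(folds),
                       reps = as.integer(reps), seed = as.integer(seed),
                       model = spec$kind, scheme = encoder@scheme))
}

#' Grid specification for sequential calibration
#'
#' Parameters are scanned strictly in the order given; a value list may
#' be a function of the already-fixed parameters (used for dependent
#' ranges such as mismatches m in 0..k-1).
#'
#' @slot params named list of value vectors (or functions of the current
#'   parameter assignment returning a value vector), in scan order.
#' @slot defaults named list of values parameters hold before their own
#'   scan.
#' @slot objective `"auroc"` or `"acc"`.
#' @exportClass GridSpec
setClass("GridSpec",
  representation(params = "list", defaults = "list",
                 objective = "character"))

setValidity("GridSpec", function(object) {
  if (!length(object@params) || is.null(names(object@params)) ||
      any(!nzchar(names(object@params))))
    return("params must be a non-empty named list")
  if (!object@objective %in% c("auroc", "acc"))
    return("objective must be 'auroc' or 'acc'")
  TRUE
})

#' @rdname GridSpec-class
#' @param params,defaults,objective see slots.
#' @export
gridSpec <- function(params, defaults = list(),
                     objective = c("auroc", "acc")) {
  new("GridSpec", params = params, defaults = defaults,
      objective = match.arg(objective))
}

setMethod("show", "GridSpec", function(object) {
  sizes <- vapply(object@params, function(v)
    if (is.function(v)) NA_integer_ else length(v), integer(1))
  cat(sprintf("GridSpec: %s (objective %s)\n",
              paste(sprintf("%s[%s]", names(object@params),
                            ifelse(is.na(sizes), "adaptive", sizes)),
                    collapse = " -> "), object@objective))
})

#' Preset calibration grids
#'
#' The scan ranges used for calibration: features — k-mer k = 1..6;
#' mismatch k = 1..6 then m = 0..k-1; subsequence k = 2..4 and
#' delta = 0.1..0.9 step 0.1; PseDSSPC d = 1..10, lambda = 1..20,
#' w = 0.1..0.9 step 0.1. Single tree — splitter best/random, depth
#' 3..10, max features 3..n. Boosting — trees 50..500 step 10, learning
#' rate 0.1..0.5 step 0.02, depth 3..10, L2 lambda 0..2 step 0.1
#' (objective AUROC; the feature/tree grids target accuracy).
#'
#' @param name one of `"kmer"`, `"mismatch"`, `"subsequence"`,
#'   `"psedsspc"`, `"cart"`, `"xgb"`.
#' @param n feature dimension; required for the `"cart"` grid's max
#'   features range.
#' @return a [GridSpec-class].
#' @export
presetGrid <- function(name = c("kmer", "mismatch", "subsequence",
                                "psedsspc", "cart", "xgb"), n = NULL) {
  name <- match.arg(name)
  switch(name,
    kmer = gridSpec(list(k = 1:6), objective = "acc"),
    mismatch = gridSpec(
      list(k = 1:6, m = function(cur) 0:(cur$k - 1L)),
      defaults = list(m = 0L), objective = "acc"),
    subsequence = gridSpec(
      list(k = 2:4, delta = seq(0.1, 0.9, by = 0.1)),
      defaults = list(delta = 0.5), objective = "acc"),
    psedsspc = gridSpec(
      list(d = 1:10, lambda = 1:20, w = seq(0.1, 0.9, by = 0.1)),
      defaults = list(lambda = 1L, w = 0.5), objective = "acc"),
    cart = {
      if (is.null(n))
        stop("the 'cart' grid needs the feature dimension n", call. = FALSE)
      gridSpec(
        list(splitter = c("best", "random"), maxDepth = 3:10,
             maxFeatures = seq(3L, as.integer(n))),
        defaults = list(splitter = "best", maxDepth = 6L,
                        maxFeatures = as.integer(n)),
        objective = "acc")
    },
    xgb = gridSpec(
      list(nTrees = seq(50L, 500L, by = 10L),
           learningRate = seq(0.1, 0.5, by = 0.02),
           maxDepth = 3:10,
           regLambda = seq(0, 2, by = 0.1)),
      defaults = list(nTrees = 100L, learningRate = 0.3,
                      maxDepth = 6L, regLambda = 1),
      objective = "auroc"))
}

#' Sequential (coordinate-wise) grid search
#'
#' Scans the grid's parameters strictly in order: while a parameter is
#' scanned, the parameters after it sit at their defaults and the ones
#' before it at their already-fixed best values. Ties break toward the
#' first-listed value, biasing toward simpler settings when value lists
#' are ordered simple-first. The full scan trace is returned for audit.
#'
#' @param grid a [GridSpec-class].
#' @param objectiveFn `function(params) -> numeric` (higher is better);
#'   `params` is a named list covering the grid's parameter names.
#' @return list with `best` (named list), `bestObjective`, and `trace`
#'   (data.frame: param, value, objective, one row per evaluated cell).
#' @export
sequentialGridSearch <- function(grid, objectiveFn) {
  stopifnot(is(grid, "GridSpec"), is.function(objectiveFn))
  current <- grid@defaults
  trace <- data.frame(param = character(0), value = character(0),
                      objective = numeric(0), stringsAsFactors = FALSE)
  bestObjective <- NA_real_
  for (p in names(grid@params)) {
    vals <- grid@params[[p]]
    if (is.function(vals)) vals <- vals(current)
    if (!length(vals))
      stop("empty value list for parameter '", p, "'", call. = FALSE)
    objs <- numeric(length(vals))
    for (i in seq_along(vals)) {
      cand <- current
      cand[[p]] <- vals[[i]]
      objs[i] <- tryCatch(objectiveFn(cand), error = function(e)
        stop(sprintf("objective evaluation failed at %s=%s: %s",
                     p, format(vals[[i]]), conditionMessage(e)),
             call. = FALSE))
      trace <- rbind(trace, data.frame(
        param = p, value = format(vals[[i]]), objective = objs[i],
        stringsAsFactors = FALSE))
    }
    bestI <- which.max(objs)          # first-listed wins on ties
    current[[p]] <- vals[[bestI]]
    bestObjective <- objs[bestI]
  }
  list(best = current, bestObjective = bestObjective, trace = trace)
}

#' LOOCV objective for grid calibration
#'
#' Builds the `objectiveFn` that [sequentialGridSearch()] evaluates: the
#' candidate parameter list is split by name into encoder parameters
#' (k, m, delta, d, lambda, w) and model hyper-parameters, and the chosen
#' metric of a pooled [loocv()] run is returned.
#'
#' @param dataset a [LabeledRnaSet-class].
#' @param scheme encoder scheme name.
#' @param kind `"boosted"` or `"single_tree"`.
#' @param metric `"acc"` or `"auroc"`.
#' @param seed integer seed for every LOOCV fold.
#' @param encoderDefaults,modelDefaults fixed parameter values not under
#'   scan.
#' @param structures,energyTable forwarded to [batchEncode()].
#' @return a function `params -> metric value`.
#' @export
loocvObjective <- function(dataset, scheme, kind = c("boosted",
                                                     "single_tree"),
                           metric = c("acc", "auroc"), seed = 1L,
                           encoderDefaults = list(), modelDefaults = list(),
                           structures = NULL,
                           energyTable = defaultEnergyTable()) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  encFields <- c("k", "m", "delta", "d", "lambda", "w")
  function(params) {
    encArgs <- utils::modifyList(encoderDefaults,
                                 params[intersect(names(params), encFields)])
    modArgs <- utils::modifyList(modelDefaults,
                                 params[setdiff(names(params), encFields)])
    enc <- do.call(encoderParams, c(list(scheme = scheme), encArgs))
    rep <- loocv(dataset, enc, spec = do.call(modelSpec,
                                              c(list(kind = kind), modArgs)),
                 seed = seed, structures = structures,
                 energyTable = energyTable)
    unname(perfMetrics(rep)[metric])
  }
}

#' Serialize a metrics report (or k-fold summary) as JSON
#'
#' @param report a [MetricsReport-class] or the list returned by
#'   [repeatedKfold()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeMetricsJson <- function(report, path) {
  payload <- if (is(report, "MetricsReport")) {
    list(metrics = as.list(perfMetrics(report)),
         counts = as.list(confusionCounts(report)),
         zeroDenominator = as.list(zeroDenomFlags(report)),
         cutoff = report@cutoff,
         protocol = report@protocol)
  } else if (is.list(report) && !is.null(report$mean)) {
    list(meanMetrics = as.list(report$mean),
         protocol = report$protocol,
         perRep = lapply(report$reports, function(r)
           c(as.list(perfMetrics(r)), as.list(confusionCounts(r)))))
  } else stop("unsupported report object", call. = FALSE)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!file.rename(tmp, path))
    stop("cannot write report to ", path, call. = FALSE)
  invisible(path)
}

#' Write a grid-search trace as TSV
#'
#' @param result the list returned by [sequentialGridSearch()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTraceTsv <- function(result, path) {
  utils::write.table(result$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
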