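#' @import methods
#' @importFrom Biostrings RNAStringSet readBStringSet writeXStringSet width
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats setNames predict runif
#' @importFrom utils modifyList packageVersion read.table write.table
#' @importClassesFrom Biostrings RNAStringSet XStringSet
#' @exportMethod show length dim
NULL

## The ten per-residue structural status categories: four unpaired nucleotides
## plus the six ordered canonical/wobble pair types. Order is fixed package-wide
## (it defines PseDSSPC feature-dimension identity).
STATUS_LEVELS <- c("A", "C", "G", "U",
                   "A-U", "U-A", "G-C", "C-G", "G-U", "U-G")

RNA_BASES <- c("A", "C", "G", "U")

ENCODER_SCHEMES <- c("kmer", "mismatch", "subsequence", "triplet", "psedsspc")

#' Encoder parameter bundle
#'
#' Holds the scheme name and the tunable parameters of one feature encoder.
#' Fields a scheme does not use are `NA`. Valid ranges follow the calibration
#' grids: `kmer` k in 1..6; `mismatch` k in 1..6, m in 0..k-1; `subsequence`
#' k in 2..4, decay delta in \[0, 1\] (the calibration grid uses 0.1..0.9;
#' delta = 0 is additionally allowed and reduces the encoder to contiguous
#' k-mer counts); `psedsspc` d in 1..10, lambda in 1..20, weight w in (0, 1\].
#'
#' @slot scheme one of `"kmer"`, `"mismatch"`, `"subsequence"`, `"triplet"`,
#'   `"psedsspc"`.
#' @slot k,m,d,lambda integer parameters (see above).
#' @slot delta,w numeric parameters (see above).
#' @exportClass EncoderParams
setClass("EncoderParams",
  representation(scheme = "character",
                 k = "integer", m = "integer",
                 delta = "numeric",
                 d = "integer", lambda = "integer", w = "numeric"),
  prototype(k = NA_integer_, m = NA_integer_, delta = NA_real_,
            d = NA_integer_, lambda = NA_integer_, w = NA_real_))

setValidity("EncoderParams", function(object) {
  s <- object@scheme
  if (length(s) != 1L || !s %in% ENCODER_SCHEMES)
    return(sprintf("scheme must be one of: %s",
                   paste(ENCODER_SCHEMES, collapse = ", ")))
  bad <- function(msg) msg
  chk_int <- function(x, lo, hi, nm) {
    if (is.na(x) || x < lo || x > hi)
      sprintf("%s must be an integer in [%d, %d]", nm, lo, hi) else TRUE
  }
  if (s %in% c("kmer", "mismatch", "subsequence")) {
    r <- chk_int(object@k, if (s == "subsequence") 2L else 1L,
                 if (s == "subsequence") 4L else 6L, "k")
    if (!isTRUE(r)) return(r)
  }
  if (s == "mismatch") {
    if (is.na(object@m) || object@m < 0L || object@m > object@k - 1L)
      return(bad("m must be an integer in [0, k-1]"))
  }
  if (s == "subsequence") {
    if (is.na(object@delta) || object@delta < 0 || object@delta > 1)
      return(bad("delta must lie in [0, 1]"))
  }
  if (s == "psedsspc") {
    r <- chk_int(object@d, 1L, 10L, "d"); if (!isTRUE(r)) return(r)
    r <- chk_int(object@lambda, 1L, 20L, "lambda"); if (!isTRUE(r)) return(r)
    if (is.na(object@w) || object@w <= 0 || object@w > 1)
      return(bad("w must lie in (0, 1]"))
  }
  TRUE
})

#' Construct encoder parameters
#'
#' @param scheme encoder scheme name.
#' @param k,m,delta,d,lambda,w scheme parameters; see [EncoderParams-class].
#' @return an [EncoderParams-class] object.
#' @examples
#' encoderParams("kmer", k = 3)
#' encoderParams("psedsspc", d = 5, lambda = 5, w = 0.5)
#' @export
encoderParams <- function(scheme, k = NA, m = NA, delta = NA,
                          d = NA, lambda = NA, w = NA) {
  new("EncoderParams", scheme = as.character(scheme),
      k = as.integer(k), m = as.integer(m), delta = as.numeric(delta),
      d = as.integer(d), lambda = as.integer(lambda), w = as.numeric(w))
}

#' Feature-vector dimension of an encoder
#'
#' 4^k for the three string-kernel schemes, 32 for the structural triplet
#' composition, 10 + 100 d + lambda for PseDSSPC.
#'
#' @param params an [EncoderParams-class].
#' @return integer dimension.
#' @export
featureDim <- function(params) {
  stopifnot(is(params, "EncoderParams"))
  switch(params@scheme,
    kmer = ,
    mismatch = ,
    subsequence = as.integer(4L^params@k),
    triplet = 32L,
    psedsspc = 10L + 100L * params@d + params@lambda)
}

setMethod("show", "EncoderParams", function(object) {
  used <- switch(object@scheme,
    kmer = sprintf("k=%d", object@k),
    mismatch = sprintf("k=%d, m=%d", object@k, object@m),
    subsequence = sprintf("k=%d, delta=%g", object@k, object@delta),
    triplet = "(no parameters)",
    psedsspc = sprintf("d=%d, lambda=%d, w=%g",
                       object@d, object@lambda, object@w))
  cat(sprintf("EncoderParams: %s %s [dim %d]\n",
              object@scheme, used, featureDim(object)))
})

#' Feature matrix with encoder provenance
#'
#' One row per sequence, columns named after the feature each dimension
#' measures (the k-mer string, the triplet pattern, the status pair and
#' distance, the correlation tier). All rows share the same
#' [EncoderParams-class] provenance; the column count always equals
#' [featureDim()] of that provenance.
#'
#' @slot values numeric matrix, rownames = sequence ids.
#' @slot params the shared [EncoderParams-class].
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", params = "EncoderParams"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (ncol(v) != featureDim(object@params))
    return(sprintf("matrix has %d columns but the %s encoder emits %d",
                   ncol(v), object@params@scheme, featureDim(object@params)))
  if (nrow(v) > 0) {
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)) ||
        any(!nzchar(rownames(v))))
      return("rownames must be unique non-empty sequence ids")
    if (!all(is.finite(v))) return("all feature values must be finite")
  }
  TRUE
})

#' @rdname FeatureMatrix-class
#' @param values numeric matrix (rownames = sequence ids).
#' @param params shared [EncoderParams-class] provenance.
#' @export
featureMatrix <- function(values, params) {
  new("FeatureMatrix", values = values, params = params)
}

#' @describeIn FeatureMatrix-class the numeric matrix.
#' @param x a `FeatureMatrix`.
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureMatrix-class the shared encoder provenance.
#' @export
featureParams <- function(x) x@params

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d sequences x %d features (%s)\n",
              nrow(object@values), ncol(object@values),
              object@params@scheme))
})

setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' Labeled pre-miRNA dataset
#'
#' Index-aligned container of RNA sequences, binary essentiality labels
#' (1 = essential = positive class, 0 = non-essential) and, optionally,
#' per-sequence dot-bracket secondary structures.
#'
#' @slot sequences an [Biostrings::RNAStringSet] with unique non-empty names.
#' @slot labels integer vector in \{0, 1\}, one per sequence.
#' @slot structures named character vector of dot-bracket strings; either
#'   empty or one per sequence, each the same length as its sequence.
#' @exportClass LabeledRnaSet
setClass("LabeledRnaSet",
  representation(sequences = "RNAStringSet", labels = "integer",
                 structures = "character"),
  prototype(structures = character(0)))

setValidity("LabeledRnaSet", function(object) {
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    return("sequence ids must be unique and non-empty")
  if (length(object@labels) != n)
    return("labels and sequences must have the same length")
  if (n > 0 && !all(object@labels %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  st <- object@structures
  if (length(st) > 0) {
    if (length(st) != n || !identical(names(st), ids))
      return("structures must be named identically to the sequences")
    if (any(nchar(st) != Biostrings::width(object@sequences)))
      return("each structure must match its sequence length")
  }
  TRUE
})

#' @rdname LabeledRnaSet-class
#' @param sequences an `RNAStringSet` with names.
#' @param labels vector coercible to integer 0/1.
#' @param structures optional named character vector of dot-bracket strings.
#' @export
labeledRnaSet <- function(sequences, labels, structures = character(0)) {
  new("LabeledRnaSet", sequences = sequences,
      labels = as.integer(labels), structures = structures)
}

#' @describeIn LabeledRnaSet-class the `RNAStringSet` of sequences.
#' @param x a `LabeledRnaSet`.
#' @export
rnaSequences <- function(x) x@sequences

#' @describeIn LabeledRnaSet-class the 0/1 essentiality labels.
#' @export
essLabels <- function(x) x@labels

#' @describeIn LabeledRnaSet-class the dot-bracket structures (may be empty).
#' @export
dotBrackets <- function(x) x@structures

setMethod("length", "LabeledRnaSet", function(x) length(x@sequences))

setMethod("show", "LabeledRnaSet", function(object) {
  cat(sprintf(
    "LabeledRnaSet: %d sequences (%d essential, %d non-essential)%s\n",
    length(object@sequences), sum(object@labels == 1L),
    sum(object@labels == 0L),
    if (length(object@structures)) ", with structures" else ""))
})

#' Per-residue structural status track
#'
#' For each residue: its status category (the nucleotide itself when
#' unpaired, or the ordered pair type X-Y when paired with a Y at the
#' partner position) and the pseudo free energy looked up for that status.
#'
#' @slot status character vector over the 10 categories
#'   A, C, G, U, A-U, U-A, G-C, C-G, G-U, U-G.
#' @slot energy numeric vector, `energy[i]` a function of `status[i]` only.
#' @exportClass StatusTrack
setClass("StatusTrack",
  representation(status = "character", energy = "numeric"))

setValidity("StatusTrack", function(object) {
  if (length(object@status) != length(object@energy))
    return("status and energy must have the same length")
  if (!all(object@status %in% STATUS_LEVELS))
    return("status values must be among the 10 allowed categories")
  TRUE
})

setMethod("length", "StatusTrack", function(x) length(x@status))

setMethod("show", "StatusTrack", function(object) {
  cat(sprintf("StatusTrack: %d residues (%d paired, %d unpaired)\n",
              length(object@status), sum(grepl("-", object@status)),
              sum(!grepl("-", object@status))))
})

#' @describeIn StatusTrack-class the per-residue categories.
#' @param x a `StatusTrack`.
#' @export
statusOf <- function(x) x@status

#' @describeIn StatusTrack-class the per-residue pseudo energies.
#' @export
energyOf <- function(x) x@energy

setClassUnion("EncoderParamsOrNULL", c("EncoderParams", "NULL"))

#' Fitted classification model
#'
#' Wraps either a single Gini-criterion classification tree or a
#' gradient-boosted tree ensemble, together with full provenance: the
#' model hyper-parameters, the encoder provenance of the training features,
#' and the seed. Predictions are deterministic given the fitted state.
#'
#' @slot kind `"single_tree"` or `"boosted"`.
#' @slot modelParams named list of hyper-parameters.
#' @slot encoderParams [EncoderParams-class] of the training features, or
#'   `NULL` when the model was trained on a bare matrix.
#' @slot seed integer seed used in training.
#' @slot fit opaque fitted state.
#' @slot engine engine name/version string.
#' @slot schemaVersion persistence schema version.
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(kind = "character", modelParams = "list",
                 encoderParams = "EncoderParamsOrNULL", seed = "integer",
                 fit = "ANY", engine = "character",
                 schemaVersion = "character"))

setValidity("TrainedModel", function(object) {
  if (!object@kind %in% c("single_tree", "boosted"))
    return("kind must be 'single_tree' or 'boosted'")
  TRUE
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s on %s features [%s] seed=%d\n",
              object@kind,
              if (is.null(object@encoderParams)) "unspecified"
              else object@encoderParams@scheme,
              object@engine, object@seed))
})

#' @describeIn TrainedModel-class encoder provenance of the training features.
#' @param x a `TrainedModel`.
#' @export
modelEncoderParams <- function(x) x@encoderParams

#' @describeIn TrainedModel-class the hyper-parameter list.
#' @export
modelParams <- function(x) x@modelParams

#' Cross-validation / test performance report
#'
#' Confusion counts at the 0.5 cutoff plus accuracy, precision, recall,
#' F1 and AUROC, with the evaluation protocol that produced them.
#' Precision, recall or F1 with a zero denominator are reported as 0 with
#' the corresponding flag set.
#'
#' @slot counts named integer vector TP, TN, FP, FN.
#' @slot metrics named numeric vector acc, pre, rec, f1, auroc.
#' @slot flags named logical vector pre, rec, f1 (TRUE = zero denominator).
#' @slot protocol list describing the protocol (e.g. loocv, kfold).
#' @slot cutoff score threshold used for hard labels.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(counts = "integer", metrics = "numeric",
                 flags = "logical", protocol = "list", cutoff = "numeric"))

setValidity("MetricsReport", function(object) {
  if (!identical(names(object@counts), c("TP", "TN", "FP", "FN")))
    return("counts must be named TP, TN, FP, FN")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (!identical(names(object@metrics), c("acc", "pre", "rec", "f1", "auroc")))
    return("metrics must be named acc, pre, rec, f1, auroc")
  m <- object@metrics
  if (any(!is.na(m) & (m < -1e-12 | m > 1 + 1e-12)))
    return("metrics must lie in [0, 1]")
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  m <- object@metrics
  cat(sprintf(
    "MetricsReport (%s): Acc=%.3f Pre=%.3f Rec=%.3f F1=%.3f AUROC=%.3f\n",
    if (length(object@protocol)) object@protocol[[1]] else "scores",
    m["acc"], m["pre"], m["rec"], m["f1"], m["auroc"]))
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n",
              object@counts["TP"], object@counts["TN"],
              object@counts["FP"], object@counts["FN"]))
})

#' @describeIn MetricsReport-class the five performance statistics.
#' @param x a `MetricsReport`.
#' @export
perfMetrics <- function(x) x@metrics

#' @describeIn MetricsReport-class the confusion counts.
#' @export
confusionCounts <- function(x) x@counts

#' @describeIn MetricsReport-class zero-denominator flags for pre/rec/f1.
#' @export
zeroDenomFlags <- function(x) x@flags
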