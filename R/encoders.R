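## The five feature encoders. Dimension identities are fixed package-wide:
## k-mer types are ordered lexicographically with A < C < G < U; triplet bins
## iterate the center nucleotide (A,C,G,U) over the 8 collapsed pairing
## patterns; PseDSSPC stacks status frequencies, distance-indexed ordered
## status pairs, then energy correlation tiers.

#' All k-mers of length k in lexicographic order (A < C < G < U)
#'
#' @param k word length.
#' @return character vector of 4^k k-mer strings.
#' @export
kmerNames <- function(k) {
  stopifnot(k >= 1)
  grid <- expand.grid(rep(list(RNA_BASES), k), stringsAsFactors = FALSE)
  do.call(paste0, grid[rev(seq_len(k))])
}

## residues -> integer codes 0..3 (A,C,G,U); errors on anything else
.baseCodes <- function(seq, id) {
  s <- toupper(as.character(seq))
  codes <- match(strsplit(s, "", fixed = TRUE)[[1]], RNA_BASES) - 1L
  if (anyNA(codes))
    stop(sprintf("'%s': sequence contains non-A/C/G/U residues", id),
         call. = FALSE)
  codes
}

## 1-based index of each length-k window into the lexicographic k-mer order
.windowIndices <- function(codes, k) {
  l <- length(codes)
  n <- l - k + 1L
  idx <- integer(n)
  for (j in seq_len(k))
    idx <- idx + codes[j:(j + n - 1L)] * 4L^(k - j)
  idx + 1L
}

.checkLen <- function(l, k, id) {
  if (l < k)
    stop(sprintf("'%s': sequence length %d is shorter than k = %d",
                 id, l, k), call. = FALSE)
}

#' k-mer frequency features
#'
#' The frequency of each of the 4^k contiguous k-mer types among the
#' l - k + 1 windows of the sequence; the vector sums to 1.
#'
#' @param seq RNA sequence (character or `RNAString`).
#' @param k word length, 1..6.
#' @param id record id for messages.
#' @return named numeric vector of length 4^k.
#' @examples
#' encodeKmer("ACGU", 1)             # 0.25 each
#' encodeKmer("ACAC", 2)[c("AC", "CA")]  # 2/3, 1/3
#' @export
encodeKmer <- function(seq, k, id = "sequence") {
  validObject(encoderParams("kmer", k = k))
  codes <- .baseCodes(seq, id)
  .checkLen(length(codes), k, id)
  counts <- tabulate(.windowIndices(codes, k), nbins = 4L^k)
  stats::setNames(counts / (length(codes) - k + 1L), kmerNames(k))
}

## digit matrix of all 4^k types, used by the mismatch neighbourhood sums
.typeDigits <- function(k) {
  n <- 4L^k
  D <- matrix(0L, n, k)
  v <- 0:(n - 1L)
  for (j in k:1) {                     # column j = j-th residue of the type
    D[, j] <- v %% 4L
    v <- v %/% 4L
  }
  D
}

#' Mismatch-count features
#'
#' For each of the 4^k k-mer types, the number of length-k windows of the
#' sequence within Hamming distance m of that type (the exact-j mismatch
#' occurrence counts summed over j = 0..m). Raw counts, not normalized;
#' with m = 0 this is exactly the contiguous k-mer count vector.
#'
#' @param seq RNA sequence.
#' @param k word length, 1..6.
#' @param m maximum mismatches, 0..k-1.
#' @param id record id for messages.
#' @return named numeric vector of length 4^k.
#' @export
encodeMismatch <- function(seq, k, m, id = "sequence") {
  validObject(encoderParams("mismatch", k = k, m = m))
  codes <- .baseCodes(seq, id)
  .checkLen(length(codes), k, id)
  counts <- tabulate(.windowIndices(codes, k), nbins = 4L^k)
  if (m == 0)
    return(stats::setNames(as.numeric(counts), kmerNames(k)))
  D <- .typeDigits(k)
  out <- numeric(4L^k)
  for (t in which(counts > 0L)) {
    dist <- rowSums(D != matrix(D[t, ], nrow(D), k, byrow = TRUE))
    out[dist <= m] <- out[dist <= m] + counts[t]
  }
  stats::setNames(out, kmerNames(k))
}

#' Gap-weighted subsequence features
#'
#' For each k-mer type, the sum over all ordered (possibly gapped) index
#' tuples p1 < ... < pk whose residues spell the type, of a decay weight:
#' a contiguous match contributes `delta^0 = 1` exactly; a gapped match
#' contributes `delta^(pk - p1 + 1)`, the string length of the matched
#' span. `delta = 0` therefore reduces to the contiguous k-mer counts.
#'
#' Computed by a prefix dynamic program over positions (exact, no
#' approximation); an exhaustive tuple-enumeration twin backs it in the
#' test suite.
#'
#' @param seq RNA sequence.
#' @param k word length, 2..4.
#' @param delta decay factor in \[0, 1\].
#' @param id record id for messages.
#' @return named numeric vector of length 4^k.
#' @examples
#' encodeSubsequence("ACA", 2, 0.5)[c("AC", "CA", "AA")]  # 1, 1, 0.125
#' @export
encodeSubsequence <- function(seq, k, delta, id = "sequence") {
  validObject(encoderParams("subsequence", k = k, delta = delta))
  codes <- .baseCodes(seq, id)
  l <- length(codes)
  .checkLen(l, k, id)
  ## M[[prefix]][p] = sum over tuples spelling `prefix` and ending at p
  ## of delta^(p - p1); extended one residue at a time via the linear
  ## recurrence S[p] = delta * (S[p-1] + M[p-1]).
  level <- lapply(0:3, function(b) as.numeric(codes == b))
  if (k > 1) {
    for (j in 2:k) {
      nxt <- vector("list", 4L^j)
      for (pre in seq_along(level)) {
        M <- level[[pre]]
        S <- numeric(l)
        for (p in 2:l) S[p] <- delta * (S[p - 1L] + M[p - 1L])
        for (b in 0:3)
          nxt[[(pre - 1L) * 4L + b + 1L]] <- (codes == b) * S
      }
      level <- nxt
    }
  }
  total <- delta * vapply(level, sum, numeric(1))
  contig <- tabulate(.windowIndices(codes, k), nbins = 4L^k)
  ## replace the contiguous tuples' delta^k weight with the exact weight 1
  out <- total - contig * delta^k + contig
  stats::setNames(out, kmerNames(k))
}

## the 8 collapsed pairing patterns in fixed order ('.' before '(')
TRIPLET_PATTERNS <- c("...", "..(", ".(.", ".((",
                      "(..", "(.(", "((.", "(((")

#' Names of the 32 structural triplet bins
#' @return character vector, e.g. `"A..."`: center nucleotide + pattern.
#' @export
tripletNames <- function() {
  as.vector(t(outer(RNA_BASES, TRIPLET_PATTERNS, paste0)))
}

#' Structural triplet composition
#'
#' For each interior position i = 2..l-1, the local pattern is the three
#' bracket symbols at i-1, i, i+1 with bracket direction collapsed
#' (`)` mapped to `(`, so each position is just paired/unpaired — 8
#' patterns), combined with the center nucleotide — 32 bins. Frequencies
#' are normalized by the l - 2 windows and sum to 1.
#'
#' @param seq RNA sequence, length >= 3.
#' @param brackets its dot-bracket structure.
#' @param id record id for messages.
#' @return named numeric vector of length 32.
#' @export
encodeTriplet <- function(seq, brackets, id = "sequence") {
  codes <- .baseCodes(seq, id)
  l <- length(codes)
  if (l < 3)
    stop(sprintf("'%s': triplet features need length >= 3 (got %d)", id, l),
         call. = FALSE)
  if (nchar(brackets) != l)
    stop(sprintf("'%s': structure length %d != sequence length %d",
                 id, nchar(brackets), l), call. = FALSE)
  dotBracketPairs(brackets, id = id)
  paired <- strsplit(chartr(")", "(", brackets), "", fixed = TRUE)[[1]] == "("
  i <- 2:(l - 1L)
  ## pattern index 0..7 with '(' as the 1-bit, left symbol most significant
  pat <- 4L * paired[i - 1L] + 2L * paired[i] + paired[i + 1L]
  bins <- codes[i] * 8L + pat + 1L
  counts <- tabulate(bins, nbins = 32L)
  stats::setNames(counts / (l - 2L), tripletNames())
}

#' Names of the PseDSSPC feature dimensions
#' @param d maximum status-pair distance.
#' @param lambda number of correlation tiers.
#' @return character vector of length 10 + 100 d + lambda.
#' @export
psedsspcNames <- function(d, lambda) {
  pairs <- as.vector(t(outer(STATUS_LEVELS, STATUS_LEVELS,
                             function(x, y) paste0(x, ">", y))))
  c(STATUS_LEVELS,
    unlist(lapply(seq_len(d), function(dd) paste0(pairs, "@", dd))),
    paste0("tier", seq_len(lambda)))
}

#' Pseudo distance-structure-status-pair composition (PseDSSPC)
#'
#' Three stacked blocks, jointly normalized:
#' \enumerate{
#'   \item the frequencies of the 10 structural statuses (count / l);
#'   \item for each distance d' = 1..d and each ordered status pair (X, Y),
#'     the frequency of positions i with status X at i and Y at i + d',
#'     normalized by the l - d' available pairs (100 dimensions per
#'     distance);
#'   \item for each tier kk = 1..lambda, the mean squared difference of the
#'     per-residue pseudo energies at lag kk.
#' }
#' With Z = sum(blocks 1-2) + w * sum(block 3), the emitted vector is
#' blocks 1-2 divided by Z and block 3 multiplied by w / Z, so the whole
#' vector sums to 1.
#'
#' @param track a [StatusTrack-class] from [assignStatus()].
#' @param d maximum pair distance, 1..10.
#' @param lambda number of correlation tiers, 1..20.
#' @param w balancing weight in (0, 1\].
#' @param id record id for messages.
#' @return named numeric vector of length 10 + 100 d + lambda.
#' @export
encodePseDSSPC <- function(track, d, lambda, w, id = "sequence") {
  validObject(encoderParams("psedsspc", d = d, lambda = lambda, w = w))
  stopifnot(is(track, "StatusTrack"))
  l <- length(track)
  if (l <= max(d, lambda))
    stop(sprintf(
      "'%s': length %d must exceed max(d, lambda) = %d for PseDSSPC",
      id, l, max(d, lambda)), call. = FALSE)
  sidx <- match(statusOf(track), STATUS_LEVELS)
  e <- energyOf(track)
  freq <- tabulate(sidx, nbins = 10L) / l
  pairBlock <- numeric(100L * d)
  for (dd in seq_len(d)) {
    i <- seq_len(l - dd)
    cells <- (sidx[i] - 1L) * 10L + sidx[i + dd]
    pairBlock[(dd - 1L) * 100L + seq_len(100L)] <-
      tabulate(cells, nbins = 100L) / (l - dd)
  }
  tiers <- vapply(seq_len(lambda), function(kk) {
    i <- seq_len(l - kk)
    sum((e[i] - e[i + kk])^2) / (l - kk)
  }, numeric(1))
  z <- sum(freq) + sum(pairBlock) + w * sum(tiers)
  out <- c(freq / z, pairBlock / z, w * tiers / z)
  stats::setNames(out, psedsspcNames(d, lambda))
}

#' Encode a sequence collection into a feature matrix
#'
#' Applies one encoder to every sequence. Structure-aware schemes
#' (`triplet`, `psedsspc`) need a dot-bracket structure for every
#' sequence, either passed explicitly or carried by the
#' [LabeledRnaSet-class]. Per-sequence failures are collected and the
#' batch aborts reporting every failing id.
#'
#' @param sequences a named [Biostrings::RNAStringSet], named character
#'   vector, or [LabeledRnaSet-class].
#' @param params an [EncoderParams-class].
#' @param structures named character vector of dot-bracket strings
#'   (required by `triplet`/`psedsspc` unless `sequences` carries them).
#' @param energyTable per-status energies for `psedsspc`
#'   ([defaultEnergyTable()]).
#' @return a [FeatureMatrix-class], rows in input order.
#' @examples
#' fm <- batchEncode(c(a = "ACGUACGU", b = "GGGCCCAA"),
#'                   encoderParams("kmer", k = 2))
#' dim(fm)
#' @export
batchEncode <- function(sequences, params, structures = NULL,
                        energyTable = defaultEnergyTable()) {
  stopifnot(is(params, "EncoderParams"))
  if (is(sequences, "LabeledRnaSet")) {
    if (is.null(structures) && length(dotBrackets(sequences)))
      structures <- dotBrackets(sequences)
    sequences <- rnaSequences(sequences)
  }
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("sequences must carry unique non-empty names", call. = FALSE)
  needsStructure <- params@scheme %in% c("triplet", "psedsspc")
  if (needsStructure) {
    if (is.null(structures))
      stop("scheme '", params@scheme, "' requires structures ",
           "(fold with foldRna() or load with readDotBracket())",
           call. = FALSE)
    missing <- setdiff(ids, names(structures))
    if (length(missing))
      stop("missing structure for id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  encodeOne <- function(id) {
    switch(params@scheme,
      kmer = encodeKmer(seqs[[id]], params@k, id = id),
      mismatch = encodeMismatch(seqs[[id]], params@k, params@m, id = id),
      subsequence = encodeSubsequence(seqs[[id]], params@k, params@delta,
                                      id = id),
      triplet = encodeTriplet(seqs[[id]], structures[[id]], id = id),
      psedsspc = encodePseDSSPC(
        assignStatus(seqs[[id]], structures[[id]], energyTable, id = id),
        params@d, params@lambda, params@w, id = id))
  }
  rows <- vector("list", length(ids))
  failures <- character(0)
  for (i in seq_along(ids)) {
    rows[[i]] <- tryCatch(encodeOne(ids[i]), error = function(e) {
      failures[[length(failures) + 1L]] <<- conditionMessage(e)
      NULL
    })
  }
  if (length(failures))
    stop("encoding failed for ", length(failures), " sequence(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  featureMatrix(values, params)
}

#' Write a feature matrix as annotated TSV
#'
#' Header comment lines (`#`) carry the encoder provenance as JSON; the
#' body is an `id` column plus one named column per feature dimension.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFeatureTsv <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  p <- fm@params
  prov <- list(scheme = p@scheme, k = p@k, m = p@m, delta = p@delta,
               d = p@d, lambda = p@lambda, w = p@w,
               dim = featureDim(p),
               encoder = paste0("essMiR ",
                                as.character(utils::packageVersion("essMiR"))))
  prov <- prov[!vapply(prov, function(x) is.na(x[1]), logical(1))]
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# provenance: ",
                    jsonlite::toJSON(prov, auto_unbox = TRUE)), con)
  df <- data.frame(id = rownames(fm@values), fm@values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  close(con)
  on.exit()
  if (!file.rename(tmp, path))
    stop("cannot write features to ", path, call. = FALSE)
  invisible(path)
}
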