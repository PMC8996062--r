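## Deterministic synthetic data: random RNAs with controlled GC content,
## hairpins that carry their own ground-truth dot-bracket (so the structural
## encoders are testable without a folding engine), and labeled datasets with
## a planted discriminative motif. Everything is a pure function of its
## arguments including the seed. The planted signal is a sufficiency probe
## for the pipeline, not a model of miRNA biology.

#' Random RNA sequence with controlled GC content
#'
#' Residues are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(U) = (1 - gc)/2`.
#'
#' @param length sequence length, >= 1.
#' @param gc GC content in (0, 1).
#' @param seed optional integer seed; same seed, same sequence.
#' @return a character string over A/C/G/U.
#' @export
randomRna <- function(length, gc = 0.5, seed = NULL) {
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)", call. = FALSE)
  draw <- function() {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  }
  if (is.null(seed)) draw() else .withSeed(seed, draw())
}

#' Random hairpin with known ground-truth structure
#'
#' The 5' stem and the loop are random; the 3' stem is the reverse
#' complement of the 5' stem (A-U, G-C), so the returned structure
#' `"(" * stemLen + "." * loopLen + ")" * stemLen` pairs only canonical
#' Watson-Crick partners and [assignStatus()] never errors on it.
#'
#' @param stemLen stem length, >= 1.
#' @param loopLen loop length, >= 3 (shorter loops are sterically
#'   impossible).
#' @param gc GC content of the random parts.
#' @param seed optional integer seed.
#' @return list with `sequence` and `structure` character strings.
#' @examples
#' hairpinRna(4, 4, seed = 7)$structure  # "((((....))))"
#' @export
hairpinRna <- function(stemLen, loopLen, gc = 0.5, seed = NULL) {
  if (stemLen < 1) stop("stemLen must be >= 1", call. = FALSE)
  if (loopLen < 3) stop("loopLen must be >= 3", call. = FALSE)
  draw <- function() list(stem5 = randomRna(stemLen, gc),
                          loop = randomRna(loopLen, gc))
  parts <- if (is.null(seed)) draw() else .withSeed(seed, draw())
  stem5 <- parts$stem5
  loop <- parts$loop
  stem3 <- chartr("ACGU", "UGCA",
                  paste(rev(strsplit(stem5, "")[[1]]), collapse = ""))
  list(sequence = paste0(stem5, loop, stem3),
       structure = paste0(strrep("(", stemLen), strrep(".", loopLen),
                          strrep(")", stemLen)))
}

#' Labeled dataset with a planted discriminative motif
#'
#' Positives (label 1) receive the motif at a uniform-random position with
#' probability `insertionRate` (overwriting the residues there); negatives
#' (label 0) are rejection-sampled until they do not contain the motif.
#' The default scale — 100 + 100 sequences of 60–90 nt — mimics the size
#' regime of curated pre-miRNA essentiality sets (order 10^2 hairpins of
#' ~60–110 nt) while keeping leave-one-out runs fast.
#'
#' @param nPos,nNeg class sizes.
#' @param lengthRange two integers, min and max sequence length.
#' @param motif planted RNA motif, shorter than the minimum length.
#' @param insertionRate probability a positive receives the motif.
#' @param gc background GC content.
#' @param seed integer seed; generation is a pure function of the
#'   arguments.
#' @param maxTries rejection-sampling budget per negative.
#' @return a [LabeledRnaSet-class] (positives first).
#' @export
plantedMotifDataset <- function(nPos = 100L, nNeg = 100L,
                                lengthRange = c(60L, 90L),
                                motif = "GGGCCC", insertionRate = 1,
                                gc = 0.5, seed = 1L, maxTries = 1000L) {
  stopifnot(nPos >= 1, nNeg >= 1, length(lengthRange) == 2,
            lengthRange[1] <= lengthRange[2])
  if (insertionRate < 0 || insertionRate > 1)
    stop("insertionRate must lie in [0, 1]", call. = FALSE)
  motif <- chartr("T", "U", toupper(motif))
  if (!grepl("^[ACGU]+$", motif))
    stop("motif must be an A/C/G/U string", call. = FALSE)
  if (nchar(motif) >= lengthRange[1])
    stop("motif must be shorter than the minimum sequence length",
         call. = FALSE)
  seqs <- .withSeed(seed, {
    lens <- sample(lengthRange[1]:lengthRange[2], nPos + nNeg,
                   replace = TRUE)
    out <- character(nPos + nNeg)
    for (i in seq_len(nPos)) {
      s <- randomRna(lens[i], gc)
      if (stats::runif(1) <= insertionRate) {
        at <- sample.int(lens[i] - nchar(motif) + 1L, 1L)
        substr(s, at, at + nchar(motif) - 1L) <- motif
      }
      out[i] <- s
    }
    for (i in nPos + seq_len(nNeg)) {
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        s <- randomRna(lens[i], gc)
        if (!grepl(motif, s, fixed = TRUE)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not sample a motif-free negative in ", maxTries,
             " tries; use a longer (rarer) motif", call. = FALSE)
      out[i] <- s
    }
    out
  })
  ids <- c(sprintf("pos_%03d", seq_len(nPos)),
           sprintf("neg_%03d", seq_len(nNeg)))
  rna <- Biostrings::RNAStringSet(seqs)
  names(rna) <- ids
  labeledRnaSet(rna, c(rep(1L, nPos), rep(0L, nNeg)))
}
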