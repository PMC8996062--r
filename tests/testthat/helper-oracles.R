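# Brute-force oracle twins of the five encoders plus a pair-counting AUROC.
# Deliberately naive (windows, exhaustive Hamming, exhaustive tuple
# enumeration, explicit loops): they define the expected values; the package
# implementations are checked against them, never the other way round.

oracleKmer <- function(seq, k) {
  l <- nchar(seq)
  wins <- substring(seq, 1:(l - k + 1), k:l)
  counts <- table(factor(wins, levels = kmerNames(k)))
  as.numeric(counts) / (l - k + 1)
}

oracleMismatch <- function(seq, k, m) {
  l <- nchar(seq)
  wins <- substring(seq, 1:(l - k + 1), k:l)
  winChars <- strsplit(wins, "")
  types <- kmerNames(k)
  typeChars <- strsplit(types, "")
  vapply(typeChars, function(tc) {
    sum(vapply(winChars, function(wc) sum(wc != tc) <= m, logical(1)))
  }, numeric(1))
}

oracleSubsequence <- function(seq, k, delta) {
  l <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  out <- setNames(numeric(4^k), kmerNames(k))
  tuples <- utils::combn(l, k)
  for (j in seq_len(ncol(tuples))) {
    p <- tuples[, j]
    word <- paste(chars[p], collapse = "")
    span <- p[k] - p[1]
    w <- if (span == k - 1) 1 else delta^(span + 1)
    out[word] <- out[word] + w
  }
  as.numeric(out)
}

oracleTriplet <- function(seq, brackets) {
  l <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  sym <- strsplit(brackets, "")[[1]]
  sym[sym == ")"] <- "("
  out <- setNames(numeric(32), tripletNames())
  for (i in 2:(l - 1)) {
    bin <- paste0(chars[i], sym[i - 1], sym[i], sym[i + 1])
    out[bin] <- out[bin] + 1
  }
  as.numeric(out) / (l - 2)
}

oraclePseDSSPC <- function(status, energy, d, lambda, w) {
  levels10 <- c("A", "C", "G", "U",
                "A-U", "U-A", "G-C", "C-G", "G-U", "U-G")
  l <- length(status)
  g1 <- numeric(10)
  for (i in seq_len(l))
    g1[match(status[i], levels10)] <- g1[match(status[i], levels10)] + 1
  g1 <- g1 / l
  g2 <- numeric(0)
  for (dd in seq_len(d)) {
    block <- numeric(100)
    for (i in seq_len(l - dd)) {
      x <- match(status[i], levels10)
      y <- match(status[i + dd], levels10)
      block[(x - 1) * 10 + y] <- block[(x - 1) * 10 + y] + 1
    }
    g2 <- c(g2, block / (l - dd))
  }
  g3 <- numeric(lambda)
  for (kk in seq_len(lambda)) {
    s <- 0
    for (i in seq_len(l - kk)) s <- s + (energy[i] - energy[i + kk])^2
    g3[kk] <- s / (l - kk)
  }
  z <- sum(g1) + sum(g2) + w * sum(g3)
  c(g1 / z, g2 / z, w * g3 / z)
}

# AUROC as the fraction of correctly ordered positive-negative pairs,
# ties counted one half.
oracleAuroc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Category counts as a plain named integer vector in name order (strips
# table() dimnames so count multisets compare cleanly).
countsOf <- function(x) {
  t <- table(x)
  setNames(as.integer(t), names(t))[sort(names(t))]
}

# Uniform random RNA string (test-local; independent of the fixtures module).
randomSeqChr <- function(l) {
  paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
}

# Trivially separable labeled set: essential sequences are G-rich, the rest
# A-rich, so even 1-mer frequencies split them perfectly.
makeSeparableSet <- function(nPerClass = 8, len = 30, seed = 42) {
  set.seed(seed)
  pos <- vapply(seq_len(nPerClass), function(i)
    paste(sample(c("G", "C"), len, replace = TRUE, prob = c(.8, .2)),
          collapse = ""), character(1))
  neg <- vapply(seq_len(nPerClass), function(i)
    paste(sample(c("A", "U"), len, replace = TRUE, prob = c(.8, .2)),
          collapse = ""), character(1))
  seqs <- Biostrings::RNAStringSet(c(pos, neg))
  names(seqs) <- c(sprintf("p%02d", seq_len(nPerClass)),
                   sprintf("n%02d", seq_len(nPerClass)))
  labeledRnaSet(seqs, rep(c(1L, 0L), each = nPerClass))
}
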