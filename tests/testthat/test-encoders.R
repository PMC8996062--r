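test_that("k-mer frequencies match hand-enumerated windows", {
  expect_equal(unname(encodeKmer("ACGU", 1)), rep(0.25, 4))
  k2 <- encodeKmer("AAAA", 2)
  expect_equal(unname(k2["AA"]), 1)
  expect_equal(sum(k2), 1)
  k3 <- encodeKmer("ACAC", 2)
  expect_equal(unname(k3[c("AC", "CA")]), c(2 / 3, 1 / 3))
  expect_equal(sum(k3 > 0), 2)
  expect_error(encodeKmer("AC", 3, id = "s1"), "s1.*length 2.*k = 3")
})

test_that("mismatch counts equal the exhaustive Hamming enumeration", {
  mm <- encodeMismatch("ACG", 2, 1)
  expect_equal(unname(mm["AC"]), 1)  # CG is at distance 2 from AC
  expect_equal(unname(mm["AG"]), 2)  # AC and CG both at distance 1
  mm2 <- encodeMismatch("AAAA", 2, 1)
  expect_equal(unname(mm2["AA"]), 3)
  expect_equal(unname(mm2[c("AC", "AG", "AU", "CA", "GA", "UA")]),
               rep(3, 6))
  expect_equal(unname(mm2["CC"]), 0)
})

test_that("subsequence sums weight gapped matches by span length", {
  ss <- encodeSubsequence("ACA", 2, 0.5)
  expect_equal(unname(ss[c("AC", "CA", "AA")]), c(1, 1, 0.125))
  ss2 <- encodeSubsequence("AAA", 2, 0.5)
  expect_equal(unname(ss2["AA"]), 2.125)
  expect_error(encodeSubsequence("ACGU", 2, 1.5), "delta")
})

test_that("fast encoders equal their brute-force twins on random RNAs", {
  set.seed(20)
  for (rep in 1:40) {
    l <- sample(4:12, 1)
    s <- randomSeqChr(l)
    k <- sample(1:min(4, l), 1)
    expect_equal(unname(encodeKmer(s, k)), oracleKmer(s, k),
                 tolerance = 1e-12)
    m <- sample(0:(k - 1), 1)
    expect_equal(unname(encodeMismatch(s, k, m)), oracleMismatch(s, k, m),
                 tolerance = 1e-12)
    if (l >= 2) {
      ks <- sample(2:min(4, l), 1)
      delta <- sample(seq(0.1, 0.9, 0.1), 1)
      expect_equal(unname(encodeSubsequence(s, ks, delta)),
                   oracleSubsequence(s, ks, delta), tolerance = 1e-12)
    }
  }
})

test_that("degeneracy identities hold exactly", {
  set.seed(30)
  for (rep in 1:10) {
    s <- randomSeqChr(sample(6:15, 1))
    k <- sample(2:4, 1)
    counts <- unname(encodeKmer(s, k)) * (nchar(s) - k + 1)
    expect_identical(unname(encodeMismatch(s, k, 0)), counts)
    expect_identical(unname(encodeSubsequence(s, k, 0)), counts)
  }
})

test_that("triplet composition collapses bracket direction over 32 bins", {
  tp <- encodeTriplet("ACGU", "....")
  expect_length(tp, 32)
  expect_equal(unname(tp[c("C...", "G...")]), c(0.5, 0.5))
  expect_equal(sum(tp), 1)
  tp2 <- encodeTriplet("GAAC", "(..)")
  expect_equal(unname(tp2[c("A(..", "A..(")]), c(0.5, 0.5))
  set.seed(40)
  for (rep in 1:10) {
    hp <- hairpinRna(sample(2:5, 1), sample(3:6, 1))
    got <- encodeTriplet(hp$sequence, hp$structure)
    expect_equal(unname(got), oracleTriplet(hp$sequence, hp$structure),
                 tolerance = 1e-12)
    expect_equal(sum(got), 1)
  }
  expect_error(encodeTriplet("AC", ".."), "length >= 3")
})

test_that("PseDSSPC matches its definition and the printed dimensions", {
  tr <- assignStatus(strrep("A", 10), strrep(".", 10))
  v <- encodePseDSSPC(tr, 1, 1, 0.5)
  expect_equal(unname(v["A"]), 0.5)
  expect_equal(unname(v["A>A@1"]), 0.5)
  expect_equal(unname(v["tier1"]), 0)
  expect_length(encodePseDSSPC(assignStatus(randomSeqChr(30),
                                            strrep(".", 30)),
                               5, 5, 0.5), 515)
  set.seed(50)
  for (rep in 1:10) {
    hp <- hairpinRna(3, 4)
    tr <- assignStatus(hp$sequence, hp$structure)
    d <- sample(1:3, 1); lam <- sample(1:3, 1)
    w <- sample(seq(0.1, 0.9, 0.1), 1)
    got <- encodePseDSSPC(tr, d, lam, w)
    expect_equal(unname(got),
                 oraclePseDSSPC(statusOf(tr), energyOf(tr), d, lam, w),
                 tolerance = 1e-12)
    expect_equal(sum(got), 1)  # joint normalization sums to one
  }
  # constant-energy track has zero correlation in every tier
  flat <- assignStatus("ACGUACGUAC", "..........")
  tiers <- encodePseDSSPC(flat, 2, 3, 0.5)[c("tier1", "tier2", "tier3")]
  expect_equal(unname(tiers), rep(0, 3))
  expect_error(encodePseDSSPC(tr, 10, 10, 0.5, id = "q"), "q.*exceed")
})

test_that("boundary lengths are legal one-window inputs", {
  expect_equal(sum(encodeKmer("ACG", 3)), 1)
  expect_equal(sum(encodeTriplet("ACG", "...")), 1)
  tr <- assignStatus("ACG", "...")
  expect_length(encodePseDSSPC(tr, 2, 2, 0.5), 212)
})

test_that("appending a residue adds exactly one window's worth of counts", {
  set.seed(60)
  for (rep in 1:5) {
    s <- randomSeqChr(10)
    s2 <- paste0(s, "G")
    k <- sample(1:3, 1)
    diff <- encodeMismatch(s2, k, 0) - encodeMismatch(s, k, 0)
    expect_true(all(diff >= 0))
    expect_equal(sum(diff), 1)
  }
})

test_that("batch encoding aligns rows, shares provenance, collects failures", {
  seqs <- c(a = "ACGUACGU", b = "GGGCCCAA", c = "AUAUAUGC")
  fm <- batchEncode(seqs, encoderParams("kmer", k = 2))
  expect_s4_class(fm, "FeatureMatrix")
  expect_identical(dim(fm), c(3L, 16L))
  expect_identical(rownames(featureValues(fm)), names(seqs))
  expect_error(batchEncode(c(a = "ACGUACGU", shorty = "AC"),
                           encoderParams("kmer", k = 3)),
               "shorty")
  expect_error(batchEncode(seqs, encoderParams("triplet")),
               "requires structures")
  st <- c(a = "((....))", b = "........")
  expect_error(batchEncode(seqs, encoderParams("triplet"), structures = st),
               "c")
})

test_that("feature TSV carries provenance and named columns", {
  fm <- batchEncode(c(a = "ACGUACGU", b = "GGGCCCAA"),
                    encoderParams("kmer", k = 2))
  out <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTsv(fm, out)
  lines <- readLines(out)
  expect_match(lines[1], "^# provenance: .*\"scheme\":\"kmer\"")
  body <- read.delim(out, comment.char = "#", check.names = FALSE)
  expect_identical(names(body)[1:3], c("id", "AA", "AC"))
  expect_identical(nrow(body), 2L)
})

test_that("encoder parameter ranges are enforced", {
  expect_error(encoderParams("kmer", k = 7), "k must")
  expect_error(encoderParams("mismatch", k = 3, m = 3), "m must")
  expect_error(encoderParams("subsequence", k = 5, delta = 0.5), "k must")
  expect_error(encoderParams("psedsspc", d = 11, lambda = 1, w = 0.5),
               "d must")
  expect_error(encoderParams("psedsspc", d = 1, lambda = 1, w = 0), "w must")
  expect_silent(encoderParams("subsequence", k = 2, delta = 0))
})
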