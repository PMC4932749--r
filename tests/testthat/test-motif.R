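test_that("frequency matrices normalise per position", {
  fm <- buildFrequencyMatrix(c("UAGG", "UAGG"))
  expect_equal(unname(freqMatrix(fm)["U", 1]), 1.0)
  expect_equal(unname(freqMatrix(fm)["G", 3]), 1.0)
  fm2 <- buildFrequencyMatrix(c("UAGG", "CAGG"))
  expect_equal(unname(freqMatrix(fm2)["U", 1]), 0.5)
  expect_equal(unname(freqMatrix(fm2)["C", 1]), 0.5)
  set.seed(3)
  inst <- implantedPeakSet(30, width = 7, rate = 0, seed = 3)
  expect_equal(colSums(freqMatrix(buildFrequencyMatrix(inst))),
               rep(1, 7), ignore_attr = TRUE)
  expect_error(buildFrequencyMatrix(c("UAGG", "UAG")), "same length")
  expect_error(buildFrequencyMatrix(character(0)), "at least one")
})

test_that("scoring is the exact log2 transform with the printed limits", {
  fm <- buildFrequencyMatrix(c("AAGG", "ACGG", "AGGG", "AUGG"))
  # pseudocount 0: freq 1 -> exactly 2 bits; freq 0.25 -> exactly 0
  sm0 <- buildScoringMatrix(fm, pseudocount = 0)
  expect_identical(unname(scoreMatrix(sm0)["A", 1]), 2)
  expect_equal(scoreMatrix(sm0)[, 2], c(A = 0, C = 0, G = 0, U = 0))
  # freq 0.5 -> exactly 1 bit
  fm5 <- buildFrequencyMatrix(c("AG", "AC", "TG", "TC"))
  expect_identical(unname(scoreMatrix(buildScoringMatrix(
    fm5, pseudocount = 0))["A", 1]), 1)
  # elementwise identity with an independent recomputation
  sim <- fixtureSim()
  inst <- implantedPeakSet(100, rate = 0.6, seed = 1)
  fmBig <- buildFrequencyMatrix(collectMotifInstances(inst, "TAGGGA"))
  smBig <- buildScoringMatrix(fmBig)
  expect_equal(scoreMatrix(smBig),
               log2((freqMatrix(fmBig) + 0.001) / (0.25 + 0.001)),
               tolerance = 1e-15)
  # maximum attainable per-position score bounded by log2(1/0.25)
  expect_lte(max(scoreMatrix(buildScoringMatrix(fmBig,
                                                pseudocount = 0))), 2)
})

test_that("sequence scanning equals brute-force window enumeration", {
  smx <- buildScoringMatrix(buildFrequencyMatrix(
    implantedPeakSet(50, width = 6, rate = 1, seed = 2)))
  set.seed(9)
  for (trial in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(30:200, 1),
                        replace = TRUE), collapse = "")
    thr <- runif(1, -5, 8)
    got <- scanSequence(seq, smx, threshold = thr)
    oracle <- scanOracle(seq, smx, thr)
    expect_equal(got$start, oracle$start)
    expect_equal(got$score, oracle$score, tolerance = 1e-12)
  }
})

test_that("scanning the consensus attains the matrix maximum, U and T equivalent", {
  smx <- buildScoringMatrix(buildFrequencyMatrix(c("TAGGGA", "TAGGGA")))
  cons <- consensusKmer(smx)
  expect_equal(cons, "UAGGGA")
  hit <- scanSequence(cons, smx, threshold = -Inf)
  expect_equal(hit$score, maxScore(smx), tolerance = 1e-12)
  hitT <- scanSequence("TAGGGA", smx, threshold = -Inf)
  expect_equal(hitT$score, hit$score)
  # threshold above the maximum -> no hits
  expect_equal(nrow(scanSequence("TAGGGATAGGGA", smx,
                                 threshold = maxScore(smx) + 1)), 0)
  # toy 2-position matrix (U then A fixed) on UAUA: hits at 1 and 3, 4 bits
  toy <- buildScoringMatrix(buildFrequencyMatrix(c("UA", "UA")),
                            pseudocount = 0)
  hits <- scanSequence("UAUA", toy, threshold = 0)
  expect_equal(hits$start, c(1L, 3L))
  expect_equal(hits$score, c(4, 4))
})

test_that("reverse-complement sequences score unrelated (sense-only scanning)", {
  smx <- buildScoringMatrix(buildFrequencyMatrix(c("TAGGGA", "TAGGGA")))
  s <- "GGTAGGGAGG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwdBest <- max(scanSequence(s, smx, threshold = -Inf)$score)
  rcBest <- max(scanSequence(rc, smx, threshold = -Inf)$score)
  expect_gt(fwdBest, rcBest + 5)
})

test_that("k-mer enrichment finds an implanted motif and is quiet on nulls", {
  fg <- implantedPeakSet(200, rate = 0.6, seed = 4)
  bg <- dinucleotideShuffle(fg, seed = 4)
  tab <- kmerEnrichment(fg, bg)
  top6 <- tab$kmer[tab$k == 6][1]
  expect_equal(top6, "UAGGGA")
  # fold uses the 0.5 pseudocount when absent from the background
  row <- tab[tab$kmer == "UAGGGA" & tab$k == 6, ]
  nf <- sum(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(fg), 6, simplify.as = "collapsed"))
  nb <- sum(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(bg), 6, simplify.as = "collapsed"))
  expFold <- ((row$fg_count + 0.5) / (nf + 1)) /
    ((row$bg_count + 0.5) / (nb + 1))
  expect_equal(row$fold, expFold, tolerance = 1e-12)
  # foreground == background -> no k-mer near the top of the null
  nullRates <- vapply(1:10, function(s) {
    fgN <- implantedPeakSet(100, rate = 0, seed = 100 + s)
    tabN <- kmerEnrichment(fgN, fgN)
    min(tabN$fdr)
  }, numeric(1))
  expect_gte(mean(nullRates >= 0.1), 0.95)
  expect_error(kmerEnrichment(character(0), fg), "empty foreground")
})

test_that("dinucleotide shuffling preserves dinucleotide composition", {
  seqs <- implantedPeakSet(20, width = 40, rate = 0.5, seed = 6)
  sh <- dinucleotideShuffle(seqs, seed = 6)
  dn <- function(x) Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(x), 2, simplify.as = "collapsed")
  expect_equal(dn(sh), dn(seqs))
  expect_false(all(sh == seqs))
})

test_that("variant scoring reproduces the known disruption directions", {
  fg <- implantedPeakSet(200, rate = 0.6, seed = 8)
  tab <- kmerEnrichment(fg, dinucleotideShuffle(fg, seed = 8))
  smx <- buildScoringMatrix(buildFrequencyMatrix(
    collectMotifInstances(fg, tab$kmer[tab$k == 6][1])))
  # UAG -> UCG (the 2A>C mutation) disrupts the motif
  ref <- "GGUUAGGGAUU"
  ve <- variantEffect(ref, 5, "A", "C", smx)
  expect_lt(ve$delta, 0)
  # UUAGAUUU -> UUAGGGAU strengthens it
  ve2 <- variantEffect("GGUUAGAUUUGG", 7, "AUUU", "GGAU", smx)
  expect_gt(ve2$delta, 0)
  # identity variant has delta exactly 0
  ve3 <- variantEffect(ref, 5, "A", "A", smx)
  expect_equal(ve3$delta, 0)
  # mismatched reference is rejected with the position named
  expect_error(variantEffect(ref, 4, "G", "C", smx), "position 4")
})
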