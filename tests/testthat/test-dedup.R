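mkTags <- function(tagStrings, pos = 100L, std = "+", chrom = "chr1",
                   sample = "s1", dels = NULL) {
  n <- length(tagStrings)
  gr <- GRanges(chrom, IRanges(rep(pos, n), rep(pos + 29L, n)), strand = std)
  gr$name <- paste0("r", seq_len(n), "#", tagStrings)
  gr$random_tag <- tagStrings
  gr$deletions <- if (is.null(dels))
    IRanges::IntegerList(rep(list(integer(0)), n)) else
    IRanges::IntegerList(dels)
  gr$multi_mapping <- FALSE
  gr$sample_id <- sample
  gr
}

test_that("the uniqueness filter drops exactly the multi-mapping tags", {
  tags <- mkTags(rep("AAAAA", 10))
  tags$multi_mapping[c(2, 5, 9)] <- TRUE
  out <- filterUnique(tags)
  expect_length(out, 7)
  expect_identical(filterUnique(mkTags("AAAAA")), mkTags("AAAAA"))
  allMulti <- mkTags(rep("AAAAA", 3)); allMulti$multi_mapping <- TRUE
  expect_length(filterUnique(allMulti), 0)
})

test_that("tags within one mismatch collapse; beyond one they do not", {
  one <- collapsePcrDuplicates(mkTags(c("AACGT", "AACGA")))
  expect_length(one$tags, 1)
  expect_equal(one$report$n_molecules, 1L)
  two <- collapsePcrDuplicates(mkTags(c("AACGT", "AAGGA")))
  expect_length(two$tags, 2)
  # chain AACGT - AACGA - AACCA merges under connected components
  chain <- collapsePcrDuplicates(mkTags(c("AACGT", "AACGA", "AACCA")))
  expect_length(chain$tags, 1)
  # ... but not under greedy non-transitive clustering seeded at AACCA
  greedy <- collapsePcrDuplicates(mkTags(c("AACGT", "AACGA", "AACCA")),
                                  greedy = TRUE)
  expect_length(greedy$tags, 2)
  # representative is the lexicographically smallest tag
  expect_equal(chain$tags$random_tag, "AACCA")
})

test_that("tags at different positions, strands or samples never merge", {
  a <- mkTags("AAAAA", pos = 100L)
  b <- mkTags("AAAAA", pos = 101L)
  c2 <- mkTags("AAAAA", pos = 100L, std = "-")
  d <- mkTags("AAAAA", pos = 100L, sample = "s2")
  out <- collapsePcrDuplicates(c(a, b, c2, d))
  expect_length(out$tags, 4)
})

test_that("minus-strand grouping uses the 5' end (genomic end)", {
  # same genomic end, different starts (3' trimming variability)
  gr <- GRanges("chr1", IRanges(c(100, 105), c(150, 150)), strand = "-")
  gr$name <- c("a#AAAAA", "b#AAAAA")
  gr$random_tag <- "AAAAA"
  gr$deletions <- IRanges::IntegerList(list(integer(0), integer(0)))
  gr$multi_mapping <- FALSE
  gr$sample_id <- "s1"
  out <- collapsePcrDuplicates(gr)
  expect_length(out$tags, 1)
})

test_that("clustering equals the brute-force transitive-closure oracle", {
  set.seed(77)
  for (trial in 1:40) {
    n <- sample(2:12, 1)
    tags <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
            collapse = ""), character(1))
    got <- collapsePcrDuplicates(mkTags(tags))
    oracle <- bruteForceClusters(tags)
    expect_equal(got$report$n_molecules, length(unique(oracle)),
                 info = paste(tags, collapse = ","))
  }
})

test_that("deduplication never increases counts and is identity without duplication", {
  cfg <- simulationConfig(n_genes = 4L, pcr_duplication_mean = 0,
                          tag_error_rate = 0, seed = 31L)
  sim <- simulateGenome(cfg)
  rd <- simulateIclipReads(sim$genome, sim$truth, cfg)
  out <- collapsePcrDuplicates(rd$alignments)
  expect_lte(length(out$tags), length(rd$alignments))
  # without PCR duplication every read is one molecule, except chance tag
  # collisions of distinct molecules at one position
  tagsByPos <- split(rd$alignments$random_tag,
                     paste(seqnames(rd$alignments), strand(rd$alignments),
                           ifelse(strand(rd$alignments) == "-",
                                  end(rd$alignments),
                                  start(rd$alignments))))
  expectMol <- sum(vapply(tagsByPos, function(t)
    length(unique(bruteForceClusters(t))), integer(1)))
  expect_equal(length(out$tags), expectMol)
})

test_that("validation rejects tags that are not 5 nt", {
  bad <- mkTags("AACG")
  expect_error(collapsePcrDuplicates(bad), "5 nt")
})

test_that("crosslink assignment applies the truncation and deletion rules", {
  # + strand, span 101..130 1-based (0-based [100,130)), no deletion ->
  # site at 1-based 100 (0-based 99)
  t1 <- mkTags("AAAAA", pos = 101L)
  s1 <- assignCrosslinks(t1)
  expect_equal(start(s1$sites), 100L)
  expect_equal(as.character(strand(s1$sites)), "+")
  # deletion at 1-based 111 -> site there
  t2 <- mkTags("AAAAA", pos = 101L, dels = list(c(111L, 112L)))
  expect_equal(start(assignCrosslinks(t2)$sites), 111L)
  # - strand span 1-based 201..250 (0-based [200,250)) -> site at 251
  # (0-based 250)
  t3 <- GRanges("chr1", IRanges(201, 250), strand = "-")
  t3$name <- "m#AAAAA"; t3$random_tag <- "AAAAA"
  t3$deletions <- IRanges::IntegerList(list(integer(0)))
  t3$multi_mapping <- FALSE; t3$sample_id <- "s1"
  s3 <- assignCrosslinks(t3)
  expect_equal(start(s3$sites), 251L)
  # - strand with deletions: 5'-most in transcript orientation = highest
  t4 <- t3
  t4$deletions <- IRanges::IntegerList(list(c(220L, 221L)))
  expect_equal(start(assignCrosslinks(t4)$sites), 221L)
  # a + strand tag starting at base 1 has no preceding base -> skipped
  t5 <- mkTags("AAAAA", pos = 1L)
  s5 <- assignCrosslinks(t5)
  expect_length(s5$sites, 0)
  expect_equal(s5$n_skipped, 1L)
})

test_that("molecule counts aggregate per position and strand", {
  tags <- c(mkTags(c("AAAAA", "CCCCC", "GGGGG"), pos = 101L),
            mkTags("TTTTT", pos = 201L))
  out <- assignCrosslinks(collapsePcrDuplicates(tags)$tags)
  expect_equal(start(out$sites), c(100L, 200L))
  expect_equal(out$sites$count, c(3L, 1L))
})

test_that("crosslink recovery against simulator ground truth on both strands", {
  cfg <- simulationConfig(n_genes = 6L, truncation_fraction = 1,
                          tag_error_rate = 0, seed = 17L)
  sim <- simulateGenome(cfg)
  rd <- simulateIclipReads(sim$genome, sim$truth, cfg)
  cl <- assignCrosslinks(collapsePcrDuplicates(rd$alignments)$tags)
  truthKey <- paste(start(sim$truth$sites), strand(sim$truth$sites))
  gotKey <- paste(start(cl$sites), strand(cl$sites))
  expect_gte(mean(gotKey %in% truthKey), 0.99)
  expect_setequal(unique(as.character(strand(cl$sites))), c("+", "-"))
})

test_that("start-profile diagnostic reports offsets and handles sparse data", {
  mkFrag <- function(starts, len, std = "+") {
    gr <- GRanges("chr1", IRanges(starts, width = len), strand = std)
    gr$name <- paste0("f", seq_along(gr), "#AAAAA")
    gr$random_tag <- "AAAAA"
    gr$deletions <- IRanges::IntegerList(rep(list(integer(0)),
                                             length(gr)))
    gr$multi_mapping <- FALSE
    gr$sample_id <- "s1"
    gr
  }
  # 15 short + 10 long sharing 5' starts in one 300-nt window
  conc <- c(mkFrag(rep(c(10, 50, 90), 5), 30), mkFrag(rep(c(10, 50), 5), 41))
  out <- startProfileDiagnostic(conc)
  expect_equal(out$verdict, "start-concordant")
  expect_equal(out$table$modal_offset, 0)
  # long class shifted +5
  shift <- c(mkFrag(rep(c(10, 50, 90), 5), 30), mkFrag(rep(c(15, 55), 5), 41))
  out2 <- startProfileDiagnostic(shift)
  expect_equal(out2$table$modal_offset, 5)
  # 19 fragments per window -> insufficient data
  sparse <- c(mkFrag(rep(10, 10), 30), mkFrag(rep(10, 9), 41))
  expect_equal(startProfileDiagnostic(sparse)$verdict, "insufficient data")
})
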