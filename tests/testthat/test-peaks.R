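mkSites <- function(pos, count = 1L, std = "+", chrom = "chrS",
                    chromLen = NA) {
  si <- if (is.na(chromLen)) NULL else Seqinfo(chrom, chromLen)
  stdv <- rep_len(std, length(pos))
  gr <- if (is.null(si)) GRanges(rep_len(chrom, length(pos)),
                                 IRanges(pos, pos), strand = stdv)
        else GRanges(rep_len(chrom, length(pos)), IRanges(pos, pos),
                     strand = stdv, seqinfo = si)
  gr$count <- rep_len(as.integer(count), length(pos))
  gr$sample_id <- rep_len("s1", length(pos))
  gr
}

oneGeneAnn <- function(gStart = 1L, gEnd = 5000L, std = "+",
                       chromLen = 6000L) {
  si <- Seqinfo("chrS", chromLen)
  genes <- GRanges("chrS", IRanges(gStart, gEnd), strand = std,
                   seqinfo = si)
  names(genes) <- "g1"
  tx <- genes; mcols(tx) <- DataFrame(gene_id = "g1"); names(tx) <- "g1.t1"
  ex <- GRanges("chrS", IRanges(gStart, gEnd), strand = std,
                transcript_id = "g1.t1", seqinfo = si)
  makeGenomeAnnotation(genes, tx, ex)
}

test_that("crosslink regions are 21 nt, clipped at chromosome edges", {
  # site at 1-based 100 (0-based 99) -> 1-based 90..110
  # (= 0-based half-open [89,110))
  r <- buildRegions(mkSites(100L), flank = 10L)
  expect_equal(start(r), 90L)
  expect_equal(end(r), 110L)
  expect_equal(width(r), 21L)
  # site at 1-based 4 (0-based 3) clips to 1..14 (0-based [0,14))
  r2 <- buildRegions(mkSites(4L, chromLen = 200L))
  expect_equal(start(r2), 1L)
  expect_equal(end(r2), 14L)
  # overlapping same-strand regions merge into one candidate
  # (sites 0-based 99 and 105 -> merged 0-based [89,116) = 1-based 90..116)
  merged <- reduce(buildRegions(mkSites(c(100L, 106L))))
  expect_equal(start(merged), 90L)
  expect_equal(end(merged), 116L)
})

test_that("an unmatchable spike gets the minimal permutation p-value", {
  # 100 molecules at one position: no uniform redistribution of 100
  # molecules over ~1 kb can reach window height 100
  ann <- oneGeneAnn()
  sites <- mkSites(2500L, count = 100L, chromLen = 6000L)
  cfg <- pipelineConfig(n_permutations = 1000L, seed = 4L)
  pk <- callPeaks(sites, ann, cfg)
  expect_length(pk, 1)
  expect_equal(pk$p_value, 1 / 1001)
  expect_equal(pk$height, 100L)
  expect_equal(pk$total, 100L)
  expect_true(pk$significant)
})

test_that("scattered single molecules are not called significant", {
  ann <- oneGeneAnn()
  cfg <- pipelineConfig(n_permutations = 200L, seed = 1L)
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    pos <- sort(sample(seq(50L, 4950L), 40))
    pos <- pos[c(TRUE, diff(pos) > 21)]  # isolated sites
    pk <- callPeaks(mkSites(pos, chromLen = 6000L), ann,
                    pipelineConfig(n_permutations = 200L, seed = s))
    sum(pk$significant)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("empty input yields an empty peak set", {
  ann <- oneGeneAnn()
  pk <- callPeaks(mkSites(integer(0)), ann, pipelineConfig())
  expect_length(pk, 0)
  expect_true(all(c("height", "total", "p_value", "fdr") %in%
                    colnames(mcols(pk))))
})

test_that("peak calling is deterministic given the seed", {
  sim <- fixtureSim()
  cl <- assignCrosslinks(collapsePcrDuplicates(
    filterUnique(sim$alignments))$tags)
  cfg <- pipelineConfig(n_permutations = 200L, seed = 99L)
  a <- callPeaks(cl$sites, sim$annotation, cfg)
  b <- callPeaks(cl$sites, sim$annotation, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("BH adjustment matches the hand computation and is monotone", {
  gr <- GRanges("chrS", IRanges(c(1, 30, 60), width = 21), strand = "+")
  gr$p_value <- c(0.01, 0.02, 0.03)
  out <- adjustFdr(gr)
  expect_equal(out$fdr, c(0.03, 0.03, 0.03))
  g1 <- GRanges("chrS", IRanges(1, 21), strand = "+")
  g1$p_value <- 0.2
  expect_equal(adjustFdr(g1)$fdr, 0.2)
  # monotone in p modulo ties
  set.seed(8)
  gn <- GRanges("chrS", IRanges(seq(1, 2000, by = 40), width = 21),
                strand = "+")
  gn$p_value <- runif(length(gn))
  fdr <- adjustFdr(gn)$fdr
  expect_true(all(diff(fdr[order(gn$p_value)]) >= -1e-12))
})

test_that("overlap utilities are half-open-aware and strand-aware", {
  # 0-based [0,10) vs [5,15) -> 1-based 1..10 vs 6..15: overlap
  a <- GRanges("c", IRanges(1, 10), strand = "+")
  b <- GRanges("c", IRanges(6, 15), strand = "+")
  expect_equal(nrow(overlapSets(a, b)$pairs), 1)
  # 0-based [0,10) vs [10,20) -> 1..10 vs 11..20: no overlap
  b2 <- GRanges("c", IRanges(11, 20), strand = "+")
  expect_equal(nrow(overlapSets(a, b2)$pairs), 0)
  # opposite strands do not overlap by default
  b3 <- GRanges("c", IRanges(6, 15), strand = "-")
  expect_equal(nrow(overlapSets(a, b3)$pairs), 0)
  expect_equal(nrow(overlapSets(a, b3, ignore_strand = TRUE)$pairs), 1)
})

test_that("proximal peaks respect the 50-nt window around exons", {
  exon <- GRanges("c", IRanges(1000, 1100), strand = "+")
  exon$exon_id <- "e"
  near <- GRanges("c", IRanges(1131, 1151), strand = "+")   # 30 nt away
  far <- GRanges("c", IRanges(1152, 1172), strand = "+")    # 51 nt away
  inside <- GRanges("c", IRanges(1050, 1070), strand = "+")
  expect_length(proximalPeaks(near, exon), 1)
  expect_length(proximalPeaks(far, exon), 0)
  expect_length(proximalPeaks(inside, exon), 1)
})

test_that("planted high-count sites are recovered as significant peaks", {
  sim <- fixtureSim()
  cl <- assignCrosslinks(collapsePcrDuplicates(
    filterUnique(sim$alignments))$tags)
  pk <- callPeaks(cl$sites, sim$annotation,
                  pipelineConfig(n_permutations = 500L, seed = 2L))
  trueSites <- sim$truth$sites[sim$truth$sites$type == "site"]
  sig <- pk[pk$significant]
  expect_gte(mean(overlapsAny(trueSites, sig)), 0.9)
})
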