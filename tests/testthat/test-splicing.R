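mkCounts <- function(exon, incl_ctrl, excl_ctrl, incl_kd, excl_kd) {
  n <- length(incl_ctrl)
  data.frame(
    gene_id = "g", exon_id = exon,
    replicate = rep(seq_len(n), 2),
    condition = rep(c("control", "knockdown"), each = n),
    inclusion = c(incl_ctrl, incl_kd),
    exclusion = c(excl_ctrl, excl_kd), stringsAsFactors = FALSE)
}

test_that("PSI is the inclusion ratio, NA when unquantifiable", {
  expect_equal(computePsi(90, 10), 0.9)
  expect_equal(computePsi(0, 50), 0)
  expect_true(is.na(computePsi(0, 0)))
  expect_equal(computePsi(c(90, 0, 0), c(10, 50, 0)), c(0.9, 0, NA))
})

test_that("the pseudoinclusion log2 fold change matches hand computation", {
  cc <- compareConditions(mkCounts("e1", 25, 75, 50, 50))
  ev <- cc$events
  expect_equal(ev$psi_control, 0.25)
  expect_equal(ev$psi_knockdown, 0.5)
  # log2((0.5+0.01)/(0.25+0.01)) = log2(0.51/0.26)
  expect_equal(ev$log2fc, log2(0.51 / 0.26), tolerance = 1e-12)
  expect_equal(ev$delta_psi, 0.25)
  # equal PSIs -> exactly zero
  ev0 <- compareConditions(mkCounts("e1", 30, 70, 30, 70))$events
  expect_equal(ev0$log2fc, 0)
  expect_equal(ev0$delta_psi, 0)
})

test_that("condition PSI averages replicates, dropping unquantifiable ones", {
  cc <- compareConditions(mkCounts("e1", c(90, 80, 0), c(10, 20, 0),
                                   c(50, 50, 50), c(50, 50, 50)))
  expect_equal(cc$events$psi_control, mean(c(0.9, 0.8)))
  # a condition with no quantifiable replicate drops the event
  cc2 <- compareConditions(mkCounts("e1", c(0, 0), c(0, 0),
                                    c(50, 50), c(50, 50)))
  expect_equal(nrow(cc2$events), 0)
  expect_equal(cc2$n_dropped, 1L)
})

test_that("the pooled Fisher p equals the exhaustive hypergeometric oracle", {
  cases <- list(c(10, 90, 50, 50), c(3, 7, 8, 2), c(0, 20, 5, 15),
                c(12, 8, 7, 13), c(1, 1, 1, 1))
  for (cs in cases) {
    ev <- compareConditions(mkCounts("e", cs[1], cs[2], cs[3],
                                     cs[4]))$events
    expect_equal(ev$p_value, fisherOracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9, info = paste(cs, collapse = ","))
  }
})

test_that("events classify by direction at the BH threshold", {
  tab <- rbind(mkCounts("up", 200, 800, 500, 500),
               mkCounts("down", 500, 500, 200, 800),
               mkCounts("flat", 500, 500, 510, 490))
  ev <- classifyEvents(compareConditions(tab)$events)
  expect_equal(ev$regulation_class[ev$exon_id == "up"], "repressed")
  expect_equal(ev$regulation_class[ev$exon_id == "down"], "activated")
  expect_equal(ev$regulation_class[ev$exon_id == "flat"], "neutral")
  # a non-significant event is neutral regardless of its delta
  solo <- classifyEvents(data.frame(
    gene_id = "g", exon_id = "e", psi_control = 0.2, psi_knockdown = 0.6,
    delta_psi = 0.4, log2fc = 1, p_value = 0.5))
  expect_equal(solo$regulation_class, "neutral")
})

test_that("rank-sum comparisons agree with exact enumeration", {
  # {1,2,3} vs {4,5,6}: 20 arrangements, 2 as extreme -> p = 0.1
  expect_equal(rankSumOracle(1:3, 4:6), 0.1)
  out <- spliceSiteStrengthCompare(list(repressed = c(1, 2, 3),
                                        neutral = c(4, 5, 6)))
  expect_equal(out$p_value, 0.1, tolerance = 1e-12)
  # interleaved identical-shape distributions -> p near 1
  outSame <- spliceSiteStrengthCompare(list(repressed = c(1, 4, 5, 8),
                                            neutral = c(2, 3, 6, 7)))
  expect_gte(outSame$p_value, 0.5)
  expect_equal(outSame$p_value, rankSumOracle(c(1, 4, 5, 8), c(2, 3, 6, 7)),
               tolerance = 1e-9)
  # randomized agreement with the oracle (tie-free values)
  set.seed(12)
  for (i in 1:5) {
    x <- sample(20, 5)
    y <- sample(100, 6) / 10 + 0.05
    expect_equal(
      spliceSiteStrengthCompare(list(repressed = x,
                                     neutral = y))$p_value,
      rankSumOracle(x, y), tolerance = 1e-9)
  }
  # undersized groups are skipped with a warning
  expect_warning(
    out2 <- spliceSiteStrengthCompare(list(repressed = c(1, 2),
                                           neutral = c(4, 5, 6))),
    "skipped")
  expect_true(is.na(out2$p_value))
})

test_that("the built-in splice-site PWM separates real donors from random sequence", {
  sim <- fixtureSim()
  scorer <- trainSpliceSitePwm(sim$genome, sim$annotation, "donor")
  ex <- annExons(sim$annotation)
  internal <- ex[grepl("internal", ex$exon_class)]
  real <- scoreSpliceSites(sim$genome, sim$annotation, internal, scorer,
                           "donor")
  set.seed(4)
  rand <- vapply(1:50, function(i)
    scorer(paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
                 collapse = "")), numeric(1))
  expect_gt(mean(real), mean(rand))
})

test_that("GC content is exact on known sequences and compares groups", {
  genome <- Biostrings::DNAStringSet(c(chrT = paste0(
    strrep("A", 200), "GGCC", "ATAT", "ACGT", strrep("A", 200))))
  exons <- GRanges("chrT", IRanges(c(201, 205, 209), c(204, 208, 212)),
                   strand = "+")
  exons$regulation_class <- c("repressed", "neutral", "neutral")
  exons$exon_id <- c("a", "b", "c")
  out <- gcContentCompare(genome, exons, flank = 100)
  expect_equal(out$per_exon$gc_exon, c(1, 0, 0.5))
  expect_false(any(out$per_exon$flank_clipped))
  # flank clipped at the contig edge is flagged
  edge <- GRanges("chrT", IRanges(5, 12), strand = "+")
  edge$regulation_class <- "neutral"; edge$exon_id <- "e"
  outEdge <- gcContentCompare(genome, edge, flank = 100)
  expect_true(outEdge$per_exon$flank_clipped)
})

test_that("PSI recovery and detection power on simulated junction counts", {
  # depth 1000: estimated PSI within 0.05 of truth for 95% of exons
  cfg <- simulationConfig(n_genes = 30L, junction_depth = 1000L,
                          psi_control = 0.45, psi_knockdown = 0.7,
                          seed = 6L)
  sim <- simulateGenome(cfg)
  jc <- simulateJunctionCounts(sim$truth, cfg)
  ev <- compareConditions(jc)$events
  m <- match(ev$exon_id, sim$truth$psi$exon_id)
  err <- abs(ev$psi_control - sim$truth$psi$psi_control[m])
  expect_gte(mean(err <= 0.05), 0.95)
  # directional power at depth 100 x 3 replicates, delta 0.3
  cfgP <- simulationConfig(n_genes = 40L, junction_depth = 100L,
                           psi_control = 0.5, psi_knockdown = 0.8,
                           n_replicates = 3L, seed = 7L)
  simP <- simulateGenome(cfgP)
  evP <- classifyEvents(compareConditions(
    simulateJunctionCounts(simP$truth, cfgP))$events)
  expect_gte(mean(evP$regulation_class == "repressed"), 0.8)
})
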