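# Shared fixtures and independent oracles. Fixtures are built in code at test
# time; the heavier simulation is memoised so several files can reuse it.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

.fixtureCache <- new.env(parent = emptyenv())

# small default-condition simulation shared across test files
fixtureSim <- function(seed = 11L) {
  key <- paste0("sim", seed)
  if (!exists(key, .fixtureCache)) {
    cfg <- simulationConfig(n_genes = 8L, seed = seed)
    sim <- simulateGenome(cfg)
    rd <- simulateIclipReads(sim$genome, sim$truth, cfg)
    assign(key, c(sim, rd, list(config = cfg)), .fixtureCache)
  }
  get(key, .fixtureCache)
}

# hand-built two-gene annotation with exact coordinates (one gene per strand,
# gene2 has a cassette middle exon)
toyAnnotation <- function(chromLen = 10000L) {
  si <- Seqinfo("chrT", chromLen)
  genes <- GRanges("chrT", IRanges(c(1001, 6001), c(2500, 8000)),
                   strand = c("+", "-"), seqinfo = si)
  names(genes) <- c("g1", "g2")
  tx <- GRanges("chrT", IRanges(c(1001, 6001, 6001), c(2500, 8000, 8000)),
                strand = c("+", "-", "-"),
                gene_id = c("g1", "g2", "g2"), seqinfo = si)
  names(tx) <- c("g1.t1", "g2.t1", "g2.t2")
  ex <- GRanges("chrT",
    IRanges(c(1001, 1501, 2401,            # g1: 3 exons
              6001, 6901, 7801,            # g2.t1: 3 exons
              6001, 7801),                 # g2.t2 skips the middle exon
            c(1100, 1600, 2500,
              6100, 7000, 8000,
              6100, 8000)),
    strand = c("+", "+", "+", "-", "-", "-", "-", "-"),
    transcript_id = c("g1.t1", "g1.t1", "g1.t1",
                      "g2.t1", "g2.t1", "g2.t1", "g2.t2", "g2.t2"),
    seqinfo = si)
  makeGenomeAnnotation(genes, tx, ex)
}

toyGenome <- function(chromLen = 10000L, seed = 5L) {
  set.seed(seed)
  DNAStringSet(setNames(paste(sample(c("A", "C", "G", "T"), chromLen,
                                     replace = TRUE), collapse = ""),
                        "chrT"))
}

# brute-force transitive closure of the Hamming<=1 relation (boolean matrix
# powers), independent of the package's graph-based clustering
bruteForceClusters <- function(tags) {
  n <- length(tags)
  if (n == 1) return(1L)
  d <- outer(tags, tags, Vectorize(function(a, b)
    sum(utf8ToInt(a) != utf8ToInt(b))))
  adj <- d <= 1
  reach <- adj
  for (i in seq_len(n)) reach <- reach | (reach %*% adj) > 0
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# exact two-sided Fisher p by enumerating all 2x2 tables with the observed
# margins (hypergeometric tail sum)
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating all assignments of ranks
rankSumOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all <- c(x, y)
  r <- rank(all)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

# brute-force window scan with the raw matrices, independent of scanSequence
scanOracle <- function(seq, scoringMatrix, threshold) {
  sm <- scoreMatrix(scoringMatrix)
  w <- ncol(sm)
  ch <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  idx <- match(ch, c("A", "C", "G", "T"))
  out <- list()
  for (s in seq_len(length(idx) - w + 1)) {
    sc <- 0
    for (j in seq_len(w)) sc <- sc + sm[idx[s + j - 1], j]
    if (!is.na(sc) && sc >= threshold)
      out[[length(out) + 1L]] <- data.frame(start = s, score = sc)
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), score = numeric(0)))
  do.call(rbind, out)
}

# write lines to a temp file, return path
tmpFile <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# synthetic peak-sequence set with an implanted motif (for motif-recovery
# experiments): n sequences of the given width, i.i.d. uniform background,
# motif written at a random position in a fraction of them
implantedPeakSet <- function(n = 200L, width = 21L, motif = "TAGGGA",
                             rate = 0.6, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), character(1))
  hit <- runif(n) < rate
  for (i in which(hit)) {
    p <- sample(width - nchar(motif) + 1L, 1)
    substr(seqs[i], p, p + nchar(motif) - 1L) <- motif
  }
  seqs
}
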