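# Seeded generator for a toy genome, annotation, ground-truth binding sites,
# iCLIP reads and cassette-exon junction counts. The background genome is
# i.i.d. uniform over ACGT; the binding motif is implanted immediately
# downstream (transcript orientation) of true crosslink sites, so truncated
# reads begin at the motif. All randomness flows from config$seed.

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Simulate a toy genome, annotation and binding ground truth
#'
#' Genes alternate strands along a single synthetic chromosome, each with
#' 3-5 exons; a configurable fraction carries a cassette middle exon (skipped
#' by a second transcript). True crosslink sites are placed uniformly within
#' genes (minimum spacing 50 nt); each receives a Poisson molecule count and,
#' at \code{motif_implant_rate}, the binding motif written into the genome
#' immediately downstream of the crosslink in transcript orientation.
#' Single-molecule background crosslink events are scattered uniformly at
#' \code{background_per_kb}. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{annotation}
#'   (\code{GenomeAnnotation}) and \code{truth}: \code{sites} (width-1
#'   \code{GRanges}; \code{count}, \code{gene_id}, \code{type}
#'   (site/background), \code{has_motif}), \code{motifs} (\code{GRanges} of
#'   implanted instances) and \code{psi} (per cassette exon true inclusion
#'   per condition).
#' @export
simulateGenome <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  chrom <- "chrS"
  pad <- 200L
  cur <- pad
  geneRows <- list(); txRows <- list(); exRows <- list(); cdsRows <- list()
  casExon <- list()
  for (g in seq_len(config$n_genes)) {
    strandG <- if (g %% 2 == 1) "+" else "-"
    nEx <- sample(seq(config$n_exons_range[1], config$n_exons_range[2]), 1)
    exLen <- sample(seq(config$exon_length_range[1],
                        config$exon_length_range[2]), nEx, replace = TRUE)
    inLen <- sample(seq(config$intron_length_range[1],
                        config$intron_length_range[2]),
                    max(nEx - 1, 0), replace = TRUE)
    gid <- sprintf("gene%03d", g)
    gStart <- cur + 1L
    s <- gStart
    exS <- integer(nEx); exE <- integer(nEx)
    for (i in seq_len(nEx)) {
      exS[i] <- s; exE[i] <- s + exLen[i] - 1L
      s <- exE[i] + if (i < nEx) inLen[i] + 1L else 1L
    }
    gEnd <- exE[nEx]
    cur <- gEnd + sample(300:800, 1)
    geneRows[[g]] <- data.frame(gid, gStart, gEnd, strandG)
    tx1 <- paste0(gid, ".t1")
    txRows[[length(txRows) + 1L]] <- data.frame(tx1, gid, gStart, gEnd,
                                                strandG)
    exRows[[length(exRows) + 1L]] <- data.frame(tx1, exS, exE, strandG)
    isCas <- nEx >= 3 && runif(1) < config$fraction_cassette
    if (isCas) {
      mid <- (nEx + 1L) %/% 2L
      tx2 <- paste0(gid, ".t2")
      txRows[[length(txRows) + 1L]] <- data.frame(tx1 = tx2, gid, gStart,
                                                  gEnd, strandG)
      exRows[[length(exRows) + 1L]] <- data.frame(tx1 = tx2, exS = exS[-mid],
                                                  exE = exE[-mid], strandG)
      casExon[[length(casExon) + 1L]] <-
        data.frame(gid, start = exS[mid], end = exE[mid], strandG)
    }
    # CDS: mid of first to mid of last exon (genomic), intersected with exons
    cdsSpan <- c(exS[1] + exLen[1] %/% 2L, exE[nEx] - exLen[nEx] %/% 2L)
    cs <- pmax(exS, cdsSpan[1]); ce <- pmin(exE, cdsSpan[2])
    keep <- cs <= ce
    cdsRows[[g]] <- data.frame(tx1, cs = cs[keep], ce = ce[keep], strandG)
  }
  genomeLen <- cur + pad
  gdf <- do.call(rbind, geneRows)
  si <- Seqinfo(chrom, genomeLen)
  genes <- GRanges(chrom, IRanges(gdf$gStart, gdf$gEnd),
                   strand = gdf$strandG, seqinfo = si)
  names(genes) <- gdf$gid
  tdf <- do.call(rbind, txRows)
  tx <- GRanges(chrom, IRanges(tdf$gStart, tdf$gEnd), strand = tdf$strandG,
                gene_id = tdf$gid, seqinfo = si)
  names(tx) <- tdf$tx1
  edf <- do.call(rbind, exRows)
  ex <- GRanges(chrom, IRanges(edf$exS, edf$exE), strand = edf$strandG,
                transcript_id = edf$tx1, seqinfo = si)
  cdf <- do.call(rbind, cdsRows)
  cds <- GRanges(chrom, IRanges(cdf$cs, cdf$ce), strand = cdf$strandG,
                 transcript_id = cdf$tx1, seqinfo = si)
  ann <- makeGenomeAnnotation(genes, tx, ex, cds)

  seqChars <- sample(c("A", "C", "G", "T"), genomeLen, replace = TRUE)
  # true crosslink sites, minimum spacing 50 nt within each gene
  mlen <- nchar(config$motif)
  mchars <- strsplit(config$motif, "")[[1]]
  mcharsRc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(config$motif))), "")[[1]]
  siteList <- list(); motifList <- list()
  for (g in seq_along(genes)) {
    gs <- start(genes)[g]; ge <- end(genes)[g]
    std <- as.character(strand(genes))[g]
    n <- config$crosslink_sites_per_gene
    if (n > 0) {
      cand <- seq(gs + 20L, ge - 20L)
      pos <- integer(0)
      for (k in seq_len(n)) {
        ok <- cand[vapply(cand, function(p)
          all(abs(p - pos) >= 50L), logical(1))]
        if (length(ok) == 0) break
        pos <- c(pos, if (length(ok) == 1) ok else sample(ok, 1))
      }
      pos <- sort(pos)
      cnt <- pmax(1L, rpois(length(pos), config$molecules_per_site))
      hasMotif <- runif(length(pos)) < config$motif_implant_rate
      for (i in seq_along(pos)) {
        if (hasMotif[i]) {
          if (std == "+") {
            idx <- (pos[i] + 1L):(pos[i] + mlen)
            seqChars[idx] <- mchars
          } else {
            idx <- (pos[i] - mlen):(pos[i] - 1L)
            seqChars[idx] <- mcharsRc
          }
          motifList[[length(motifList) + 1L]] <-
            data.frame(s = min(idx), e = max(idx), std,
                       gid = names(genes)[g])
        }
      }
      siteList[[length(siteList) + 1L]] <-
        data.frame(pos, std, cnt, gid = names(genes)[g], type = "site",
                   has_motif = hasMotif)
    }
    nBg <- rpois(1, width(genes)[g] / 1000 * config$background_per_kb)
    if (nBg > 0) {
      bgPos <- sample(seq(gs + 20L, ge - 20L), nBg, replace = TRUE)
      siteList[[length(siteList) + 1L]] <-
        data.frame(pos = bgPos, std, cnt = 1L, gid = names(genes)[g],
                   type = "background", has_motif = FALSE)
    }
  }
  sdf <- do.call(rbind, siteList)
  sites <- GRanges(chrom, IRanges(sdf$pos, sdf$pos), strand = sdf$std,
                   count = sdf$cnt, gene_id = sdf$gid, type = sdf$type,
                   has_motif = sdf$has_motif, seqinfo = si)
  motifs <- if (length(motifList) > 0) {
    mdf <- do.call(rbind, motifList)
    GRanges(chrom, IRanges(mdf$s, mdf$e), strand = mdf$std,
            gene_id = mdf$gid, seqinfo = si)
  } else GRanges(seqinfo = si)

  cas <- cassetteExons(ann)
  psi <- if (length(cas) > 0) {
    data.frame(gene_id = cas$gene_id, exon_id = cas$exon_id,
               chrom = as.character(seqnames(cas)),
               start = start(cas), end = end(cas),
               psi_control = rep_len(config$psi_control, length(cas)),
               psi_knockdown = rep_len(config$psi_knockdown, length(cas)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), exon_id = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               psi_control = numeric(0), psi_knockdown = numeric(0))
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(seqChars, collapse = ""),
                                              chrom))
  list(genome = genome, annotation = ann,
       truth = list(sites = sites, motifs = motifs, psi = psi))
}

# mutate tag bases at the given per-base substitution rate
.mutateTag <- function(tag, rate) {
  if (rate <= 0) return(tag)
  ch <- strsplit(tag, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

#' Simulate iCLIP reads and their true alignments
#'
#' Every ground-truth molecule yields a cDNA that either truncates at its
#' crosslink site (read starts one base 3' of the site in transcript
#' orientation) or, with probability \code{1 - truncation_fraction}, reads
#' through the site leaving a 1-2 nt deletion there. Each molecule is
#' sequenced \code{1 + Poisson(pcr_duplication_mean)} times; duplicates carry
#' the molecule's 5-nt random tag with per-base substitution errors at
#' \code{tag_error_rate}. Raw reads are prefixed with the RRRIIIIRR barcode
#' (tag bases at the R positions, the sample identifier at the I positions)
#' and padded with adapter when the fragment is shorter than the machine read
#' length. True alignments are emitted directly so no aligner is needed.
#'
#' @param genome \code{DNAStringSet} from \code{\link{simulateGenome}}.
#' @param truth ground-truth list from \code{\link{simulateGenome}}.
#' @param config the same \code{\link{simulationConfig}}.
#' @return list: \code{reads} (data.frame name/seq/qual, raw FASTQ records),
#'   \code{alignments} (\code{GRanges} of true per-read alignments with
#'   \code{name}, \code{cigar}, \code{random_tag} (observed, post-error),
#'   \code{deletions}, \code{multi_mapping}, \code{sample_id}), and
#'   \code{read_truth} (per-read molecule id, true tag, sample, crosslink
#'   position and mode).
#' @export
simulateIclipReads <- function(genome, truth, config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.streamSeed(config$seed, 2L))
  sites <- truth$sites
  chromSeq <- as.character(genome[[1]])
  chrom <- names(genome)[1]
  chromLen <- nchar(chromSeq)
  idents <- names(config$sample_sheet)
  samples <- unname(config$sample_sheet)
  machineLen <- config$read_length_range[2]
  # expand sites to molecules
  molSite <- rep(seq_along(sites), sites$count)
  nMol <- length(molSite)
  molSample <- sample(seq_along(samples), nMol, replace = TRUE)
  recs <- vector("list", nMol)
  for (m in seq_len(nMol)) {
    s <- molSite[m]
    x <- start(sites)[s]
    std <- as.character(strand(sites))[s]
    L <- sample(seq(config$read_length_range[1],
                    config$read_length_range[2]), 1)
    trunc <- runif(1) < config$truncation_fraction
    if (trunc) {
      if (std == "+") {
        e2 <- min(x + L, chromLen)
        frag <- substr(chromSeq, x + 1L, e2)
        pos <- x + 1L
        cigar <- paste0(nchar(frag), "M")
      } else {
        s2 <- max(x - L, 1L)
        frag <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(substr(chromSeq, s2, x - 1L))))
        pos <- s2
        cigar <- paste0(nchar(frag), "M")
      }
      dels <- integer(0)
    } else {
      u <- sample(5:12, 1)
      d <- sample(1:2, 1)
      m2 <- L - u
      if (std == "+") {
        s1 <- max(x - u, 1L); e2 <- min(x + d - 1L + m2, chromLen)
        up <- substr(chromSeq, s1, x - 1L)
        dn <- substr(chromSeq, x + d, e2)
        frag <- paste0(up, dn)
        pos <- s1
        cigar <- paste0(nchar(up), "M", d, "D", nchar(dn), "M")
        dels <- x:(x + d - 1L)
      } else {
        e1 <- min(x + u, chromLen); s2 <- max(x - d + 1L - m2, 1L)
        up <- substr(chromSeq, x + 1L, e1)        # 5' part, genomic
        dn <- substr(chromSeq, s2, x - d)
        frag <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(paste0(dn, up))))
        pos <- s2
        cigar <- paste0(nchar(dn), "M", d, "D", nchar(up), "M")
        dels <- (x - d + 1L):x
      }
    }
    tag <- .randSeq(5L)
    nDup <- 1L + rpois(1, config$pcr_duplication_mean)
    recs[[m]] <- list(site = s, x = x, std = std, frag = frag, pos = pos,
                      cigar = cigar, dels = list(dels), tag = tag,
                      nDup = nDup, sample = molSample[m],
                      mode = if (trunc) "truncation" else "deletion")
  }
  nReads <- sum(vapply(recs, `[[`, integer(1), "nDup"))
  name <- character(nReads); seqv <- character(nReads)
  alnPos <- integer(nReads); alnStd <- character(nReads)
  alnCigar <- character(nReads); obsTag <- character(nReads)
  sampleId <- character(nReads); molId <- integer(nReads)
  trueTag <- character(nReads); xPos <- integer(nReads)
  mode <- character(nReads); delList <- vector("list", nReads)
  r <- 0L
  for (m in seq_len(nMol)) {
    rec <- recs[[m]]
    ident <- idents[rec$sample]
    for (k in seq_len(rec$nDup)) {
      r <- r + 1L
      tg <- .mutateTag(rec$tag, config$tag_error_rate)
      bar <- paste0(substr(tg, 1, 3), ident, substr(tg, 4, 5))
      raw <- paste0(bar, rec$frag)
      if (nchar(rec$frag) < machineLen)
        raw <- substr(paste0(raw, config$adapter),
                      1, nchar(bar) + machineLen)
      nm <- sprintf("mol%06d:d%d", m, k)
      name[r] <- nm; seqv[r] <- raw
      alnPos[r] <- rec$pos; alnStd[r] <- rec$std; alnCigar[r] <- rec$cigar
      obsTag[r] <- tg; sampleId[r] <- samples[rec$sample]
      molId[r] <- m; trueTag[r] <- rec$tag; xPos[r] <- rec$x
      mode[r] <- rec$mode; delList[[r]] <- rec$dels[[1]]
    }
  }
  reads <- data.frame(name = name, seq = seqv,
                      qual = strrep("I", nchar(seqv)),
                      stringsAsFactors = FALSE)
  walks <- lapply(alnCigar, .cigarWalk)
  span <- vapply(walks, `[[`, integer(1), "span")
  aln <- GRanges(chrom, IRanges(alnPos, alnPos + span - 1L),
                 strand = alnStd,
                 seqinfo = Seqinfo(chrom, chromLen))
  aln$name <- paste0(name, "#", obsTag)
  aln$cigar <- alnCigar
  aln$random_tag <- obsTag
  aln$deletions <- IRanges::IntegerList(delList)
  aln$multi_mapping <- FALSE
  aln$sample_id <- sampleId
  readTruth <- data.frame(name = name, molecule = molId, true_tag = trueTag,
                          sample_id = sampleId, crosslink = xPos,
                          strand = alnStd, mode = mode,
                          stringsAsFactors = FALSE)
  list(reads = reads, alignments = aln, read_truth = readTruth)
}

#' Simulate cassette-exon junction counts
#'
#' Per replicate and condition, inclusion junction reads are Binomial at
#' \code{junction_depth} around the exon's true inclusion level; exclusion
#' reads are the remainder.
#'
#' @param truth ground-truth list from \code{\link{simulateGenome}} (uses
#'   \code{truth$psi}).
#' @param config a \code{\link{simulationConfig}}.
#' @return data.frame: \code{gene_id}, \code{exon_id}, \code{replicate},
#'   \code{condition} (control/knockdown), \code{inclusion}, \code{exclusion}.
#' @export
simulateJunctionCounts <- function(truth, config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.streamSeed(config$seed, 3L))
  psi <- truth$psi
  if (nrow(psi) == 0)
    return(data.frame(gene_id = character(0), exon_id = character(0),
                      replicate = integer(0), condition = character(0),
                      inclusion = integer(0), exclusion = integer(0)))
  grid <- expand.grid(i = seq_len(nrow(psi)),
                      replicate = seq_len(config$n_replicates),
                      condition = c("control", "knockdown"),
                      stringsAsFactors = FALSE)
  p <- ifelse(grid$condition == "control",
              psi$psi_control[grid$i], psi$psi_knockdown[grid$i])
  incl <- rbinom(nrow(grid), config$junction_depth, p)
  data.frame(gene_id = psi$gene_id[grid$i], exon_id = psi$exon_id[grid$i],
             replicate = grid$replicate, condition = grid$condition,
             inclusion = incl,
             exclusion = config$junction_depth - incl,
             stringsAsFactors = FALSE)
}

#' Exact-substring aligner for error-free smoke tests
#'
#' Maps reads by exact full-length match against both strands of the toy
#' genome. Only intended for end-to-end checks of the error-free,
#' truncation-only simulation; reads containing crosslink deletions do not
#' match exactly and are dropped (and counted).
#'
#' @param reads data.frame with \code{name}, \code{seq} (post-preprocessing,
#'   barcode removed; the \code{#TAG} name suffix is carried through).
#' @param genome \code{DNAStringSet}.
#' @return list: \code{tags} (\code{GRanges} in \code{\link{readSamLite}}
#'   layout), \code{unaligned} (count).
#' @export
alignReadsExact <- function(reads, genome) {
  chrom <- names(genome)[1]
  chromLen <- Biostrings::nchar(genome)[1]
  fwd <- genome[[1]]
  rev <- Biostrings::reverseComplement(fwd)
  out <- list(); unaligned <- 0L
  for (i in seq_len(nrow(reads))) {
    p <- Biostrings::matchPattern(reads$seq[i], fwd)
    q <- Biostrings::matchPattern(reads$seq[i], rev)
    nHit <- length(p) + length(q)
    if (nHit == 0) { unaligned <- unaligned + 1L; next }
    if (length(p) > 0)
      out[[length(out) + 1L]] <- data.frame(
        name = reads$name[i], s = BiocGenerics::start(p),
        e = BiocGenerics::end(p), std = "+", multi = nHit > 1)
    if (length(q) > 0)
      out[[length(out) + 1L]] <- data.frame(
        name = reads$name[i], s = chromLen - BiocGenerics::end(q) + 1L,
        e = chromLen - BiocGenerics::start(q) + 1L, std = "-",
        multi = nHit > 1)
  }
  if (length(out) == 0) {
    tags <- GRanges()
    mcols(tags) <- S4Vectors::DataFrame(
      name = character(0), random_tag = character(0),
      deletions = IRanges::IntegerList(), multi_mapping = logical(0),
      sample_id = character(0))
    return(list(tags = tags, unaligned = unaligned))
  }
  df <- do.call(rbind, out)
  tags <- GRanges(chrom, IRanges(df$s, df$e), strand = df$std,
                  seqinfo = Seqinfo(chrom, chromLen))
  tags$name <- df$name
  tags$random_tag <- sub("^.*#", "", df$name)
  tags$deletions <- IRanges::IntegerList(
    rep(list(integer(0)), nrow(df)))
  tags$multi_mapping <- df$multi
  tags$sample_id <- "s1"
  list(tags = tags, unaligned = unaligned)
}
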