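# Peak calling on crosslink sites: +-10 nt regions, merged candidates, and a
# superlocal permutation null: the ~1-kb window's molecules are redistributed
# uniformly and the max 21-nt sliding-window count is compared with the
# observed one. BH adjustment is applied across all candidates in the run.

#' Build crosslink regions around sites
#'
#' Each crosslink site is extended by \code{flank} nt to either side (21 nt
#' at the default flank of 10), clipped at chromosome bounds.
#'
#' @param sites width-1 \code{GRanges} of crosslink sites.
#' @param flank nt added on each side (default 10).
#' @return \code{GRanges} of regions (one per site, metadata preserved).
#' @export
buildRegions <- function(sites, flank = 10L) {
  r <- suppressWarnings(sites + flank)
  if (!all(is.na(seqlengths(r)))) r <- trim(r)
  start(r) <- pmax(start(r), 1L)
  r
}

# permutation null: total molecules redistributed uniformly over L positions;
# returns n_perm maxima of the w-nt sliding-window count
.permWindowMax <- function(L, total, w, n_perm) {
  vapply(seq_len(n_perm), function(i) {
    cnt <- tabulate(sample.int(L, total, replace = TRUE), L)
    cs <- cumsum(cnt)
    if (L <= w) return(cs[L])
    max(cs[w:L] - c(0L, cs[seq_len(L - w)]))
  }, numeric(1))
}

# max w-nt sliding-window sum with window starts restricted to [from, to]
.windowMax <- function(counts, w, from, to) {
  L <- length(counts)
  cs <- cumsum(counts)
  ends <- pmin(seq(from, to) + w - 1L, L)
  starts <- seq(from, to)
  max(cs[ends] - ifelse(starts > 1L, cs[starts - 1L], 0))
}

#' Call binding peaks with a superlocal permutation null
#'
#' Crosslink sites are extended into +-\code{crosslink_flank} regions and
#' merged into candidate intervals per gene and strand (genes span their
#' pre-mRNA extent, introns included). For each candidate, the superlocal
#' background window is the candidate extended by half the configured window
#' to each side, clipped to the gene. Under the null, the window's total
#' molecule count is redistributed uniformly over its positions
#' \code{n_permutations} times; the p-value is
#' \code{(1 + #(null max 21-nt window count >= observed)) / (n + 1)}.
#' P-values are then BH-adjusted across all candidates and peaks at
#' \code{fdr <= peak_fdr} flagged significant.
#'
#' @param sites width-1 \code{GRanges} of deduplicated crosslink sites with
#'   a \code{count} column.
#' @param annotation a \code{GenomeAnnotation} (gene spans used).
#' @param config a \code{\link{pipelineConfig}} (flank, permutations, window,
#'   FDR threshold, seed).
#' @return \code{GRanges} of candidate peaks with metadata \code{gene_id},
#'   \code{height} (max per-position molecule count), \code{total}
#'   (molecules in peak), \code{p_value}, \code{fdr}, \code{significant}.
#' @export
callPeaks <- function(sites, annotation, config = pipelineConfig()) {
  emptyPeaks <- function() {
    p <- GRanges()
    mcols(p) <- S4Vectors::DataFrame(
      gene_id = character(0), height = integer(0), total = integer(0),
      p_value = numeric(0), fdr = numeric(0), significant = logical(0))
    p
  }
  if (length(sites) == 0) return(emptyPeaks())
  set.seed(.streamSeed(config$seed, 11L))
  genes <- annGenes(annotation)
  w <- 2L * config$crosslink_flank + 1L
  half <- config$superlocal_window %/% 2L
  hit <- findOverlaps(sites, genes)
  out <- list()
  for (g in unique(S4Vectors::subjectHits(hit))) {
    ii <- S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == g]
    gs <- sites[ii]
    regions <- buildRegions(gs, config$crosslink_flank)
    cands <- reduce(regions)
    gStart <- start(genes)[g]; gEnd <- end(genes)[g]
    posAll <- start(gs); cntAll <- gs$count
    for (ci in seq_along(cands)) {
      cs <- start(cands)[ci]; ce <- end(cands)[ci]
      ws <- max(cs - half, gStart, 1L)
      we <- min(ce + half, gEnd)
      L <- we - ws + 1L
      inWin <- posAll >= ws & posAll <= we
      counts <- integer(L)
      tb <- tapply(cntAll[inWin], posAll[inWin] - ws + 1L, sum)
      counts[as.integer(names(tb))] <- as.integer(tb)
      total <- sum(counts)
      from <- cs - ws + 1L
      to <- max(from, ce - ws + 1L - w + 1L)
      obs <- .windowMax(counts, w, from, to)
      nullMax <- .permWindowMax(L, total, w, config$n_permutations)
      p <- (1 + sum(nullMax >= obs)) / (config$n_permutations + 1)
      inCand <- posAll >= cs & posAll <= ce
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(seqnames(cands))[ci], start = cs, end = ce,
        strand = as.character(strand(gs))[1],
        gene_id = names(genes)[g],
        height = max(cntAll[inCand]),
        total = sum(cntAll[inCand]),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(emptyPeaks())
  df <- do.call(rbind, out)
  peaks <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                   seqinfo = seqinfo(sites))
  peaks$gene_id <- df$gene_id
  peaks$height <- df$height
  peaks$total <- df$total
  peaks$p_value <- df$p_value
  peaks <- adjustFdr(peaks, config$peak_fdr)
  .logStage("peaks", "candidates=", length(peaks), " significant=",
            sum(peaks$significant))
  sort(peaks)
}

#' Benjamini-Hochberg adjustment of peak p-values
#'
#' @param peaks \code{GRanges} with a \code{p_value} column.
#' @param fdr_threshold significance threshold on the adjusted values
#'   (default 0.1).
#' @return \code{peaks} with \code{fdr} and \code{significant} columns.
#' @export
adjustFdr <- function(peaks, fdr_threshold = 0.1) {
  peaks$fdr <- p.adjust(peaks$p_value, method = "BH")
  peaks$significant <- peaks$fdr <= fdr_threshold
  peaks
}

#' Strand-aware overlap of two interval sets
#'
#' Reports pairs with at least 1 nt same-strand overlap and how many
#' intervals of each set are involved in any overlap.
#'
#' @param a,b \code{GRanges}.
#' @param ignore_strand if \code{TRUE}, overlap regardless of strand.
#' @return list: \code{pairs} (data.frame of index pairs), \code{n_a_overlap},
#'   \code{n_b_overlap}.
#' @export
overlapSets <- function(a, b, ignore_strand = FALSE) {
  hit <- findOverlaps(a, b, minoverlap = 1L, ignore.strand = ignore_strand)
  list(pairs = data.frame(a = S4Vectors::queryHits(hit),
                          b = S4Vectors::subjectHits(hit)),
       n_a_overlap = length(unique(S4Vectors::queryHits(hit))),
       n_b_overlap = length(unique(S4Vectors::subjectHits(hit))))
}

#' Peaks inside or near exons
#'
#' Returns the peaks whose interval intersects an exon extended by
#' \code{max_distance} nt on both sides (same strand).
#'
#' @param peaks \code{GRanges} of peaks.
#' @param exons \code{GRanges} of exons (e.g. \code{cassetteExons(ann)}).
#' @param max_distance nt (default 50).
#' @return the qualifying subset of \code{peaks}.
#' @export
proximalPeaks <- function(peaks, exons, max_distance = 50L) {
  ext <- suppressWarnings(exons + max_distance)
  start(ext) <- pmax(start(ext), 1L)
  IRanges::subsetByOverlaps(peaks, ext)
}
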