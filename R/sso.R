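# SSO target selection: binding peaks whose nearest edge lies 10-40 nt
# downstream of the 5' splice site (donor) of repressed cassette exons or
# user-supplied pseudoexons, ranked by motif content x peak strength, with a
# proposed antisense RNA sequence per candidate.

# first intronic base downstream of the donor, genomic coordinate
.intronFirstBase <- function(exons) {
  ifelse(as.character(strand(exons)) == "-", start(exons) - 1L,
         end(exons) + 1L)
}

#' Find SSO candidate target sites
#'
#' For each target exon (typically the repressed cassette exons from
#' \code{\link{classifyEvents}}, or pseudoexons supplied as intervals), peaks
#' on the same strand whose nearest edge lies within \code{window} nt
#' downstream of the donor site (distance 1 = first intronic base) are
#' accepted. The target window (donor + 10 .. donor + 40 by default) is
#' scanned for motif hits; candidates are ranked by
#' \code{(sum of motif-hit scores in the window) * log2(1 + peak height)},
#' ties broken by distance (nearer first), then coordinate. Exons at a
#' contig edge without a downstream intron are skipped with a warning.
#'
#' @param peaks \code{GRanges} of significant peaks (needs \code{height}).
#' @param exons \code{GRanges} of target exons with an \code{exon_id}
#'   column (e.g. repressed cassette exons, or pseudoexon records).
#' @param matrix a \code{ScoringMatrix} for motif scoring.
#' @param genome \code{DNAStringSet}.
#' @param window accepted distance range (nt, inclusive; default 10-40).
#' @param motif_threshold minimum motif-hit score in bits (default 0).
#' @return data.frame, one row per accepted (exon, peak) pair, ranked:
#'   exon/peak coordinates, \code{distance_to_5ss}, \code{n_motif_hits},
#'   \code{motif_score_sum}, \code{rank_score}, \code{proposed_sso} (RNA),
#'   \code{sso_start}/\code{sso_end} (genomic target of the SSO).
#' @export
findSsoCandidates <- function(peaks, exons, matrix, genome,
                              window = c(10L, 40L), motif_threshold = 0) {
  stopifnot(is(matrix, "ScoringMatrix"))
  rows <- list()
  chromLens <- setNames(Biostrings::nchar(genome), names(genome))
  for (i in seq_along(exons)) {
    chrom <- as.character(seqnames(exons))[i]
    std <- as.character(strand(exons))[i]
    ib <- .intronFirstBase(exons[i])
    if (ib < 1 || ib > chromLens[chrom]) {
      warning("exon ", i, " has no annotated downstream intron; skipped")
      next
    }
    same <- peaks[seqnames(peaks) == chrom &
                    as.character(strand(peaks)) == std]
    if (length(same) == 0) next
    # distance from the first intronic base to the peak's nearest edge
    d <- if (std == "-") ib - end(same) + 1L else start(same) - ib + 1L
    acc <- which(d >= window[1] & d <= window[2])
    if (length(acc) == 0) next
    # genomic target window donor+window[1] .. donor+window[2]
    if (std == "-") {
      winS <- ib - window[2] + 1L; winE <- ib - window[1] + 1L
    } else {
      winS <- ib + window[1] - 1L; winE <- ib + window[2] - 1L
    }
    winGr <- GRanges(chrom, IRanges(max(winS, 1L),
                                    min(winE, chromLens[chrom])),
                     strand = std)
    winSeq <- extractSenseSequences(winGr, genome)
    hits <- if (nchar(winSeq) >= matrixWidth(matrix))
      scanSequence(winSeq, matrix, threshold = motif_threshold)
    else data.frame(start = integer(0), end = integer(0),
                    score = numeric(0))
    mss <- sum(hits$score)
    for (a in acc) {
      rows[[length(rows) + 1L]] <- data.frame(
        exon_id = if (!is.null(exons$exon_id)) exons$exon_id[i]
                  else as.character(i),
        chrom = chrom, strand = std,
        exon_start = start(exons)[i], exon_end = end(exons)[i],
        peak_start = start(same)[a], peak_end = end(same)[a],
        peak_height = if (!is.null(same$height)) same$height[a]
                      else NA_integer_,
        distance_to_5ss = d[a],
        window_start = start(winGr), window_end = end(winGr),
        n_motif_hits = nrow(hits), motif_score_sum = mss,
        rank_score = mss * log2(1 + (if (!is.null(same$height))
          same$height[a] else 1)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(exon_id = character(0), chrom = character(0),
                      strand = character(0), distance_to_5ss = integer(0),
                      rank_score = numeric(0),
                      proposed_sso = character(0)))
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$rank_score, cand$distance_to_5ss,
                     cand$peak_start), , drop = FALSE]
  rownames(cand) <- NULL
  sso <- lapply(seq_len(nrow(cand)), function(j)
    proposeSso(cand[j, ], genome, matrix = matrix,
               motif_threshold = motif_threshold))
  cand$proposed_sso <- vapply(sso, `[[`, character(1), "sso")
  cand$sso_start <- vapply(sso, `[[`, integer(1), "target_start")
  cand$sso_end <- vapply(sso, `[[`, integer(1), "target_end")
  cand
}

#' Propose an antisense SSO sequence for a candidate
#'
#' The shortest window within \code{length_range} covering all motif hits in
#' the candidate's target window (extended symmetrically when below the
#' minimum length, clamped with a warning when the motif span exceeds the
#' maximum) is reverse-complemented to RNA. The window never overlaps the
#' 9-nt donor recognition region (last 3 exonic + first 6 intronic nt).
#'
#' @param candidate one row of the \code{\link{findSsoCandidates}} table.
#' @param genome \code{DNAStringSet}.
#' @param length_range SSO length bounds (nt, default 18-25).
#' @param matrix a \code{ScoringMatrix} used to locate motif hits in the
#'   target window.
#' @param motif_threshold minimum motif-hit score (default 0).
#' @return list: \code{sso} (antisense RNA, 5' to 3'),
#'   \code{target_start}/\code{target_end} (genomic sense target),
#'   \code{clamped} (TRUE when the motif span exceeded the maximum length).
#' @export
proposeSso <- function(candidate, genome, length_range = c(18L, 25L),
                       matrix = NULL, motif_threshold = 0) {
  chrom <- candidate$chrom; std <- candidate$strand
  chromLen <- Biostrings::nchar(genome)[match(chrom, names(genome))]
  winGr <- GRanges(chrom, IRanges(candidate$window_start,
                                  candidate$window_end), strand = std)
  # motif hit span (genomic); fall back to the peak when no hits
  span <- NULL
  if (!is.null(matrix)) {
    winSeq <- extractSenseSequences(winGr, genome)
    hits <- if (nchar(winSeq) >= matrixWidth(matrix))
      scanSequence(winSeq, matrix, threshold = motif_threshold)
    else data.frame(start = integer(0), end = integer(0))
    if (nrow(hits) > 0) {
      hs <- if (std == "-") end(winGr) - hits$end + 1L
            else start(winGr) + hits$start - 1L
      he <- if (std == "-") end(winGr) - hits$start + 1L
            else start(winGr) + hits$end - 1L
      span <- c(min(hs), max(he))
    }
  }
  if (is.null(span))
    span <- c(max(candidate$peak_start, start(winGr)),
              min(candidate$peak_end, end(winGr)))
  # donor recognition region: exon -3 .. intron +6 (never covered)
  donorLo <- if (std == "-") candidate$exon_start - 6L
             else candidate$exon_end - 2L
  donorHi <- if (std == "-") candidate$exon_start + 2L
             else candidate$exon_end + 6L
  clamped <- FALSE
  len <- span[2] - span[1] + 1L
  if (len > length_range[2]) {
    warning("motif span (", len, " nt) exceeds the maximum SSO length; ",
            "emitting maximal-coverage SSO")
    clamped <- TRUE
    trim <- len - length_range[2]
    span <- c(span[1] + trim %/% 2L, span[2] - (trim - trim %/% 2L))
  } else if (len < length_range[1]) {
    pad <- length_range[1] - len
    span <- c(span[1] - pad %/% 2L, span[2] + (pad - pad %/% 2L))
  }
  # keep clear of the donor region and contig edges: shift, preserving width
  wlen <- span[2] - span[1] + 1L
  if (std == "-") {
    if (span[2] >= donorLo) span <- c(donorLo - wlen, donorLo - 1L)
  } else {
    if (span[1] <= donorHi) span <- c(donorHi + 1L, donorHi + wlen)
  }
  span[1] <- max(span[1], 1L); span[2] <- min(span[2], chromLen)
  sense <- extractSenseSequences(
    GRanges(chrom, IRanges(span[1], span[2]), strand = std), genome)
  list(sso = reverseComplementRna(sense),
       target_start = as.integer(span[1]),
       target_end = as.integer(span[2]), clamped = clamped)
}
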