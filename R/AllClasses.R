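#' @rdname GenomeAnnotation-class
#' @export
setGeneric("annGenes", function(x) standardGeneric("annGenes"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("annTranscripts", function(x) standardGeneric("annTranscripts"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("annExons", function(x) standardGeneric("annExons"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("annCds", function(x) standardGeneric("annCds"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("cassetteExons", function(x) standardGeneric("cassetteExons"))

#' @rdname FrequencyMatrix-class
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))

#' @rdname ScoringMatrix-class
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname FrequencyMatrix-class
#' @export
setGeneric("matrixWidth", function(x) standardGeneric("matrixWidth"))

#' @rdname FrequencyMatrix-class
#' @export
setGeneric("consensusKmer", function(x) standardGeneric("consensusKmer"))

#' @rdname ScoringMatrix-class
#' @export
setGeneric("maxScore", function(x) standardGeneric("maxScore"))
#' GenomeAnnotation: genes, transcripts and classified exons
#'
#' Lightweight container for a gene annotation. Exons carry a class label per
#' transcript context: \code{first}, \code{last}, \code{internal} and, for
#' alternative internal exons, additionally \code{cassette} (an internal exon
#' absent from at least one other transcript of the same gene). A single-exon
#' transcript's exon is labelled both \code{first} and \code{last}, never
#' \code{internal}. Coordinates are 1-based closed \code{GRanges}; GTF input
#' is converted on read.
#'
#' @slot genes \code{GRanges}, one per gene, names = gene ids.
#' @slot transcripts \code{GRanges} with metadata column \code{gene_id},
#'   names = transcript ids.
#' @slot exons \code{GRanges} with metadata columns \code{transcript_id},
#'   \code{gene_id}, \code{exon_rank} (5' to 3' in transcript orientation) and
#'   \code{exon_class} (comma-joined labels).
#' @slot cds \code{GRanges} of coding regions (may be empty), metadata column
#'   \code{transcript_id}.
#'
#' @aliases annGenes annTranscripts annExons annCds cassetteExons
#' @export
setClass("GenomeAnnotation",
  representation(
    genes       = "GRanges",
    transcripts = "GRanges",
    exons       = "GRanges",
    cds         = "GRanges"
  )
)

setValidity("GenomeAnnotation", function(object) {
  ex <- object@exons
  tx <- object@transcripts
  msg <- character(0)
  if (is.null(names(object@genes)) && length(object@genes) > 0)
    msg <- c(msg, "genes must be named by gene id")
  need <- c("transcript_id", "gene_id", "exon_rank", "exon_class")
  if (!all(need %in% colnames(S4Vectors::mcols(ex))))
    msg <- c(msg, paste("exons must carry metadata columns:",
                        paste(need, collapse = ", ")))
  if (length(msg) == 0 && length(ex) > 0) {
    hit <- match(ex$transcript_id, names(tx))
    if (anyNA(hit)) {
      msg <- c(msg, "exon refers to unknown transcript")
    } else {
      inside <- as.character(seqnames(ex)) == as.character(seqnames(tx))[hit] &
        start(ex) >= start(tx)[hit] & end(ex) <= end(tx)[hit]
      if (!all(inside))
        msg <- c(msg, sprintf("exon outside its transcript (e.g. %s)",
                              ex$transcript_id[which(!inside)[1]]))
      # non-overlapping and ordered within each transcript
      byTx <- split(seq_along(ex), ex$transcript_id)
      for (ii in byTx) {
        o <- ii[order(ex$exon_rank[ii])]
        if (length(o) > 1) {
          s <- start(ex)[o]; e <- end(ex)[o]
          minus <- as.character(strand(ex))[o[1]] == "-"
          if (minus) { s <- rev(s); e <- rev(e) }
          if (any(s[-1] <= e[-length(e)]))
            msg <- c(msg, sprintf("overlapping or unordered exons in %s",
                                  ex$transcript_id[o[1]]))
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GenomeAnnotation-class gene spans.
#' @param x a \code{GenomeAnnotation}.
#' @export
setMethod("annGenes", "GenomeAnnotation", function(x) x@genes)

#' @describeIn GenomeAnnotation-class transcript spans.
#' @export
setMethod("annTranscripts", "GenomeAnnotation", function(x) x@transcripts)

#' @describeIn GenomeAnnotation-class classified exons.
#' @export
setMethod("annExons", "GenomeAnnotation", function(x) x@exons)

#' @describeIn GenomeAnnotation-class coding regions.
#' @export
setMethod("annCds", "GenomeAnnotation", function(x) x@cds)

#' @describeIn GenomeAnnotation-class unique cassette-exon intervals
#'   (deduplicated across transcripts).
#' @export
setMethod("cassetteExons", "GenomeAnnotation", function(x) {
  ex <- x@exons
  cas <- ex[vapply(strsplit(ex$exon_class, ","), function(z)
    "cassette" %in% z, logical(1))]
  u <- unique(granges(cas))
  hit <- findOverlaps(u, cas, type = "equal", select = "first")
  u$gene_id <- cas$gene_id[hit]
  u$exon_id <- paste0(u$gene_id, ":", start(u), "-", end(u))
  u
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@genes), "genes,",
      length(object@transcripts), "transcripts,",
      length(object@exons), "exon records\n")
  ncas <- length(cassetteExons(object))
  cat("  cassette exons:", ncas, "\n")
})

.BASES_RNA <- c("A", "C", "G", "U")

#' FrequencyMatrix: per-position base frequencies of a motif
#'
#' Columns are motif positions, rows the RNA bases A, C, G, U; every column
#' sums to 1. Built from aligned equal-length motif instances with
#' \code{\link{buildFrequencyMatrix}}.
#'
#' @slot freq numeric 4 x width matrix, rownames \code{A,C,G,U}.
#' @aliases freqMatrix matrixWidth consensusKmer
#' @export
setClass("FrequencyMatrix", representation(freq = "matrix"))

setValidity("FrequencyMatrix", function(object) {
  f <- object@freq
  if (!is.numeric(f) || nrow(f) != 4 || !identical(rownames(f), .BASES_RNA))
    return("freq must be a numeric 4 x width matrix with rownames A,C,G,U")
  if (ncol(f) < 1) return("width must be >= 1")
  if (any(f < 0)) return("frequencies must be non-negative")
  if (any(abs(colSums(f) - 1) > 1e-9))
    return("each position's four frequencies must sum to 1")
  TRUE
})

#' @describeIn FrequencyMatrix-class the 4 x width frequency matrix.
#' @param x a \code{FrequencyMatrix} or \code{ScoringMatrix}.
#' @export
setMethod("freqMatrix", "FrequencyMatrix", function(x) x@freq)

#' @describeIn FrequencyMatrix-class number of motif positions.
#' @export
setMethod("matrixWidth", "FrequencyMatrix", function(x) ncol(x@freq))

#' @describeIn FrequencyMatrix-class most frequent base at each position,
#'   as an RNA string.
#' @export
setMethod("consensusKmer", "FrequencyMatrix", function(x)
  paste(.BASES_RNA[apply(x@freq, 2, which.max)], collapse = ""))

setMethod("show", "FrequencyMatrix", function(object) {
  cat("FrequencyMatrix, width", ncol(object@freq),
      " consensus", consensusKmer(object), "\n")
  print(round(object@freq, 3))
})

#' ScoringMatrix: log2 position scores against a flat background
#'
#' Per-position, per-base scores \code{log2((freq + p) / (background + p))}
#' with pseudocount \code{p}; with \code{p = 0} a base at the background
#' frequency 0.25 scores 0 and a fixed base scores exactly
#' \code{log2(1/0.25) = 2} bits. Motif hits are scored as the sum of the
#' matched bases' position scores.
#'
#' @slot score numeric 4 x width matrix, rownames \code{A,C,G,U}.
#' @slot background background base frequency used (default 0.25).
#' @slot pseudocount pseudocount added to frequencies and background.
#' @aliases scoreMatrix maxScore
#' @export
setClass("ScoringMatrix",
  representation(score = "matrix", background = "numeric",
                 pseudocount = "numeric"))

setValidity("ScoringMatrix", function(object) {
  s <- object@score
  if (!is.numeric(s) || nrow(s) != 4 || !identical(rownames(s), .BASES_RNA))
    return("score must be a numeric 4 x width matrix with rownames A,C,G,U")
  if (length(object@background) != 1 || object@background <= 0 ||
      object@background >= 1)
    return("background must be a single value in (0,1)")
  if (length(object@pseudocount) != 1 || object@pseudocount < 0)
    return("pseudocount must be a single non-negative value")
  TRUE
})

#' @describeIn ScoringMatrix-class the 4 x width score matrix (bits).
#' @param x a \code{ScoringMatrix}.
#' @export
setMethod("scoreMatrix", "ScoringMatrix", function(x) x@score)

#' @describeIn ScoringMatrix-class number of positions.
#' @export
setMethod("matrixWidth", "ScoringMatrix", function(x) ncol(x@score))

#' @describeIn ScoringMatrix-class maximum attainable window score (bits).
#' @export
setMethod("maxScore", "ScoringMatrix", function(x)
  sum(apply(x@score, 2, max)))

#' @describeIn ScoringMatrix-class highest-scoring base at each position.
#' @export
setMethod("consensusKmer", "ScoringMatrix", function(x)
  paste(.BASES_RNA[apply(x@score, 2, which.max)], collapse = ""))

setMethod("show", "ScoringMatrix", function(object) {
  cat("ScoringMatrix, width", ncol(object@score),
      " background", object@background,
      " max score", round(maxScore(object), 3), "bits\n")
  print(round(object@score, 3))
})
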