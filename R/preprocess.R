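# Read preprocessing: barcode parsing under the RRRIIIIRR scheme, exact
# demultiplexing on the 4-nt identifier, 3' running-sum quality trimming,
# adapter trimming with <= 1 mismatch, and the >= 20 nt length filter.
# Stage order follows the protocol: barcode -> quality -> adapter -> length.

#' Parse the 5' barcode and extract the random tag
#'
#' Under a scheme over \code{R} (random) and \code{I} (identifier) positions
#' (default \code{RRRIIIIRR}), the bases at the R positions are stitched
#' together in read order into the 5-nt random tag used for PCR-duplicate
#' detection, the I-position bases form the sample identifier, and the whole
#' barcode is removed from the read. The tag is appended to the read name as
#' \code{#TAG} so it survives alignment. Reads not longer than the scheme are
#' discarded and counted.
#'
#' @param reads data.frame with \code{name}, \code{seq}, \code{qual}.
#' @param scheme barcode layout string (default \code{RRRIIIIRR}).
#' @return list: \code{reads} (with added \code{sample_id}, \code{random_tag}
#'   columns, barcode removed from \code{seq}/\code{qual}, tag appended to
#'   \code{name}), \code{n_discarded}.
#' @export
parseBarcode <- function(reads, scheme = "RRRIIIIRR") {
  stopifnot(grepl("^[RI]+$", scheme))
  bl <- nchar(scheme)
  keep <- nchar(reads$seq) > bl
  dropped <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]
  pos <- strsplit(scheme, "")[[1]]
  if (nrow(reads) > 0) {
    chars <- vapply(seq_len(bl), function(i) substr(reads$seq, i, i),
                    character(nrow(reads)))
    chars <- matrix(chars, nrow = nrow(reads))
    tag <- apply(chars[, pos == "R", drop = FALSE], 1, paste, collapse = "")
    sid <- apply(chars[, pos == "I", drop = FALSE], 1, paste, collapse = "")
  } else {
    tag <- character(0); sid <- character(0)
  }
  out <- data.frame(
    name = if (nrow(reads)) paste0(reads$name, "#", tag) else character(0),
    seq = substring(reads$seq, bl + 1L),
    qual = substring(reads$qual, bl + 1L),
    sample_id = sid, random_tag = tag, stringsAsFactors = FALSE)
  list(reads = out, n_discarded = dropped)
}

#' Demultiplex reads on the sample identifier
#'
#' Reads are assigned to the sample whose 4-nt identifier exactly equals
#' their I-segment; everything else goes to the unassigned stream. Counts are
#' conserved: assigned + unassigned = input.
#'
#' @param reads data.frame from \code{\link{parseBarcode}} (needs
#'   \code{sample_id}).
#' @param sample_sheet named character vector identifier -> sample name;
#'   identifiers must be distinct.
#' @return list: \code{samples} (named list of per-sample read data.frames),
#'   \code{unassigned} (data.frame), \code{counts} (named integer vector).
#' @export
demultiplexReads <- function(reads, sample_sheet) {
  if (anyDuplicated(names(sample_sheet)))
    stop("duplicate identifier in sample sheet: ",
         names(sample_sheet)[duplicated(names(sample_sheet))][1])
  hit <- match(reads$sample_id, names(sample_sheet))
  samples <- lapply(seq_along(sample_sheet), function(i)
    reads[which(hit == i), , drop = FALSE])
  names(samples) <- unname(sample_sheet)
  unassigned <- reads[is.na(hit), , drop = FALSE]
  counts <- c(vapply(samples, nrow, integer(1)),
              unassigned = nrow(unassigned))
  list(samples = samples, unassigned = unassigned, counts = counts)
}

# trim one sequence: leftmost position whose suffix matches an adapter prefix
# (>= min_overlap, <= max_mismatch, no indels); an internal full-length match
# also truncates from its start. Returns the kept length.
.adapterCut <- function(seq, adapter, max_mismatch, min_overlap) {
  n <- nchar(seq); al <- nchar(adapter)
  sv <- utf8ToInt(seq); av <- utf8ToInt(adapter)
  for (i in seq_len(n)) {
    L <- min(n - i + 1L, al)
    if (n - i + 1L > al) {
      # internal: full adapter must match
      if (sum(sv[i:(i + al - 1L)] != av) <= max_mismatch) return(i - 1L)
    } else {
      if (L < min_overlap) break
      if (sum(sv[i:(i + L - 1L)] != av[1:L]) <= max_mismatch) return(i - 1L)
    }
  }
  n
}

#' Trim 3' adapter sequence
#'
#' Removes the longest 3'-terminal occurrence of an adapter prefix (minimum
#' overlap 3 nt) allowing up to one mismatch by default; a full internal
#' adapter match truncates the read from the match start.
#'
#' @param reads data.frame with \code{seq}, \code{qual} (or a character
#'   vector of sequences).
#' @param adapter adapter sequence (DNA).
#' @param max_mismatch allowed mismatches (default 1).
#' @param min_overlap minimum terminal overlap (default 3 nt).
#' @return same shape as \code{reads}, sequences (and qualities) truncated.
#' @export
trimAdapter <- function(reads, adapter, max_mismatch = 1L,
                        min_overlap = 3L) {
  stopifnot(nchar(adapter) > 0)
  plain <- is.character(reads)
  seqs <- if (plain) reads else reads$seq
  keepLen <- vapply(seqs, .adapterCut, integer(1), adapter = adapter,
                    max_mismatch = max_mismatch, min_overlap = min_overlap,
                    USE.NAMES = FALSE)
  if (plain) return(substr(seqs, 1L, keepLen))
  reads$seq <- substr(reads$seq, 1L, keepLen)
  reads$qual <- substr(reads$qual, 1L, keepLen)
  reads
}

# BWA-style 3' running-sum trim: cut where sum(threshold - q) from the 3' end
# is maximal (and positive)
.qualityCut <- function(qual, threshold) {
  q <- utf8ToInt(qual) - 33L
  n <- length(q)
  if (n == 0L) return(0L)
  s <- cumsum(rev(threshold - q))
  best <- which.max(s)
  if (s[best] <= 0L) n else n - best
}

#' Quality-trim read 3' ends
#'
#' Standard running-sum trimming from the 3' end at the given Phred
#' threshold (default Q20): the read is cut at the point maximising the
#' cumulative \code{threshold - q} sum over the removed tail. Output is
#' always a prefix of the input.
#'
#' @param reads data.frame with \code{seq}, \code{qual}.
#' @param threshold Phred threshold (default 20).
#' @return \code{reads} with trimmed \code{seq}/\code{qual}.
#' @export
qualityTrim <- function(reads, threshold = 20L) {
  keepLen <- vapply(reads$qual, .qualityCut, integer(1),
                    threshold = threshold, USE.NAMES = FALSE)
  reads$seq <- substr(reads$seq, 1L, keepLen)
  reads$qual <- substr(reads$qual, 1L, keepLen)
  reads
}

#' Retain reads of a minimum length
#'
#' @param reads data.frame with \code{seq}.
#' @param min_length minimum retained length (nt, default 20).
#' @return filtered \code{reads}.
#' @export
lengthFilter <- function(reads, min_length = 20L) {
  reads[nchar(reads$seq) >= min_length, , drop = FALSE]
}

#' Full preprocessing stage
#'
#' Barcode parsing, demultiplexing, quality trimming, adapter trimming and
#' length filtering, in protocol order, with a per-fate count summary.
#'
#' @param reads raw read data.frame (\code{name}, \code{seq}, \code{qual}).
#' @param sample_sheet named character vector identifier -> sample.
#' @param config a \code{\link{pipelineConfig}}.
#' @return list: \code{samples} (named list of processed per-sample reads),
#'   \code{summary} (data.frame of counts per fate).
#' @export
preprocessReads <- function(reads, sample_sheet,
                            config = pipelineConfig()) {
  pb <- parseBarcode(reads, config$barcode_scheme)
  dm <- demultiplexReads(pb$reads, sample_sheet)
  out <- lapply(dm$samples, function(rd) {
    rd <- qualityTrim(rd, config$quality_threshold)
    rd <- trimAdapter(rd, config$adapter, config$adapter_max_mismatch,
                      config$adapter_min_overlap)
    lengthFilter(rd, config$min_read_length)
  })
  summary <- data.frame(
    fate = c("input", "too_short_barcode", "unassigned",
             paste0("retained_", names(out))),
    count = c(nrow(reads), pb$n_discarded, nrow(dm$unassigned),
              vapply(out, nrow, integer(1))))
  .logStage("preprocess", "in=", nrow(reads), " retained=",
            sum(vapply(out, nrow, integer(1))))
  list(samples = out, summary = summary)
}
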