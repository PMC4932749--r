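# Motif analysis on peak sequences (sense strand only -- iCLIP is
# strand-specific): exact k-mer enrichment against a background set, a
# frequency matrix over the top k-mer and its 1-mismatch occurrences, the
# log2 scoring matrix against a flat 0.25 background, sequence scanning and
# variant-effect scoring. K-mers are reported in the RNA alphabet.

.asDnaSet <- function(x) {
  if (is(x, "DNAStringSet")) x
  else Biostrings::DNAStringSet(toupper(asDna(x)))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: each sequence is rewritten as a random Eulerian
#' walk on its dinucleotide graph, preserving the exact dinucleotide (and
#' hence mononucleotide) composition. Used to build background sets for
#' k-mer enrichment.
#'
#' @param seqs character vector or \code{DNAStringSet}.
#' @param seed integer seed.
#' @return character vector of shuffled sequences (DNA alphabet).
#' @export
dinucleotideShuffle <- function(seqs, seed = 1L) {
  set.seed(.streamSeed(seed, 21L))
  seqs <- as.character(.asDnaSet(seqs))
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    if (n <= 2) return(s)
    # edge lists: successors of each base, in sequence order
    succ <- split(ch[-1], ch[-n])
    # shuffle successor lists, keeping the last edge into the terminal base
    # reachable: retry until the walk uses all edges (small alphabet, cheap)
    for (attempt in 1:100) {
      bag <- lapply(succ, sample)
      idx <- lapply(bag, function(x) 1L)
      outDeg <- lengths(bag)
      used <- setNames(integer(length(bag)), names(bag))
      walk <- character(n); walk[1] <- ch[1]
      ok <- TRUE
      for (i in 2:n) {
        b <- walk[i - 1]
        k <- used[b] + 1L
        if (is.na(k) || k > outDeg[b]) { ok <- FALSE; break }
        walk[i] <- bag[[b]][k]
        used[b] <- k
      }
      if (ok && sum(used) == n - 1L) return(paste(walk, collapse = ""))
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Generate uniform-random background sequences
#'
#' Length-matched i.i.d. uniform ACGT sequences, the simple alternative
#' background model.
#'
#' @param seqs foreground sequences (lengths copied).
#' @param seed integer seed.
#' @return character vector of random sequences.
#' @export
uniformBackground <- function(seqs, seed = 1L) {
  set.seed(.streamSeed(seed, 22L))
  lens <- nchar(as.character(.asDnaSet(seqs)))
  vapply(lens, .randSeq, character(1))
}

#' K-mer enrichment of peak sequences over a background
#'
#' Counts every k-mer (overlapping occurrences) in the foreground and
#' background sets for each k, computes fold enrichment with a pseudocount
#' of 0.5 per cell, a one-sided binomial p-value against the background
#' occurrence rate, and a BH adjustment per k. Ranked by p-value, then fold.
#'
#' @param foreground peak sequences (character or \code{DNAStringSet},
#'   sense strand).
#' @param background length-matched background sequences (e.g.
#'   \code{\link{dinucleotideShuffle}} of the foreground).
#' @param k_values k-mer lengths (default 6, 7, 8).
#' @param pseudocount added per count cell for rates and folds (default 0.5).
#' @return data.frame: \code{k}, \code{kmer} (RNA alphabet), \code{fg_count},
#'   \code{bg_count}, \code{fold}, \code{p_value}, \code{fdr}; ranked.
#' @export
kmerEnrichment <- function(foreground, background,
                           k_values = c(6L, 7L, 8L), pseudocount = 0.5) {
  fg <- .asDnaSet(foreground)
  bg <- .asDnaSet(background)
  if (length(fg) == 0) stop("empty foreground sequence set")
  out <- list()
  for (k in k_values) {
    fc <- Biostrings::oligonucleotideFrequency(fg, width = k,
                                               simplify.as = "collapsed")
    bc <- Biostrings::oligonucleotideFrequency(bg, width = k,
                                               simplify.as = "collapsed")
    nf <- sum(fc); nb <- sum(bc)
    keep <- fc > 0
    fc <- fc[keep]; bc <- bc[keep]
    rate <- (bc + pseudocount) / (nb + 2 * pseudocount)
    fold <- ((fc + pseudocount) / (nf + 2 * pseudocount)) / rate
    p <- pbinom(fc - 1L, nf, pmin(rate, 1), lower.tail = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      k = k, kmer = asRna(names(fc)), fg_count = as.integer(fc),
      bg_count = as.integer(bc), fold = unname(fold),
      p_value = unname(p), fdr = p.adjust(unname(p), "BH"),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$p_value, -tab$fold), ]
  rownames(tab) <- NULL
  tab
}

#' Collect aligned instances of a k-mer in sequences
#'
#' All occurrences of the k-mer and of its 1-mismatch neighbours present in
#' the sequences, as equal-length ungapped instances -- the input for
#' \code{\link{buildFrequencyMatrix}}.
#'
#' @param seqs sequences (character or \code{DNAStringSet}).
#' @param kmer the k-mer (RNA or DNA spelling).
#' @param max_mismatch mismatches admitted (default 1).
#' @return character vector of instances (DNA alphabet).
#' @export
collectMotifInstances <- function(seqs, kmer, max_mismatch = 1L) {
  x <- .asDnaSet(seqs)
  pat <- toupper(asDna(kmer))
  hits <- Biostrings::vmatchPattern(pat, x, max.mismatch = max_mismatch)
  inst <- character(0)
  for (i in seq_along(x)) {
    h <- hits[[i]]
    # mismatch matching can report ranges overhanging the sequence ends
    h <- h[BiocGenerics::start(h) >= 1 &
             BiocGenerics::end(h) <= length(x[[i]])]
    if (length(h) > 0)
      inst <- c(inst, as.character(Biostrings::extractAt(x[[i]], h)))
  }
  inst
}

#' Build a frequency matrix from aligned motif instances
#'
#' Column frequencies are base counts divided by the instance count; all
#' instances must have equal length.
#'
#' @param instances character vector or \code{DNAStringSet} of equal-length
#'   sequences.
#' @return a \code{\link{FrequencyMatrix-class}} object.
#' @export
buildFrequencyMatrix <- function(instances) {
  x <- .asDnaSet(instances)
  if (length(x) == 0) stop("at least one instance is required")
  if (length(unique(Biostrings::nchar(x))) != 1)
    stop("instances must all have the same length")
  cm <- Biostrings::consensusMatrix(x, as.prob = TRUE,
                                    baseOnly = TRUE)[1:4, , drop = FALSE]
  # redistribute any non-ACGT mass uniformly so columns sum to 1
  miss <- 1 - colSums(cm)
  cm <- sweep(cm, 2, miss / 4, "+")
  rownames(cm) <- .BASES_RNA
  methods::new("FrequencyMatrix", freq = cm)
}

#' Derive the log2 scoring matrix from a frequency matrix
#'
#' \code{score[i, b] = log2((freq[i, b] + p) / (background + p))} with
#' pseudocount \code{p} (default 0.001) against a flat background (default
#' 0.25). With \code{p = 0}, a frequency of 0.25 scores 0 and a frequency of
#' 1 scores exactly 2 bits.
#'
#' @param freq a \code{FrequencyMatrix}.
#' @param background flat background base frequency (default 0.25).
#' @param pseudocount pseudocount (default 0.001; prevents -Inf at zero
#'   frequencies).
#' @return a \code{\link{ScoringMatrix-class}} object.
#' @export
buildScoringMatrix <- function(freq, background = 0.25,
                               pseudocount = 0.001) {
  stopifnot(is(freq, "FrequencyMatrix"))
  if (background <= 0 || background >= 1)
    stop("background must be in (0, 1)")
  s <- log2((freqMatrix(freq) + pseudocount) / (background + pseudocount))
  methods::new("ScoringMatrix", score = s, background = background,
               pseudocount = pseudocount)
}

# integer row indices (A=1,C=2,G=3,U/T=4) for a sequence; NA for other bases
.baseIndex <- function(seq) {
  m <- match(strsplit(toupper(asDna(seq)), "")[[1]],
             c("A", "C", "G", "T"))
  m
}

#' Scan a sequence for motif hits
#'
#' Every window of the matrix width scoring at least \code{threshold} bits is
#' reported; T and U are equivalent. Scanning is on the given sequence only
#' (sense strand); the reverse complement is never scanned.
#'
#' @param seq a single sequence (RNA or DNA spelling).
#' @param matrix a \code{ScoringMatrix}.
#' @param threshold minimum reported score in bits (default 0).
#' @param seqname name used for the hit intervals.
#' @return data.frame: \code{start}, \code{end} (1-based in \code{seq}),
#'   \code{kmer} (RNA), \code{score}; empty if none qualify.
#' @export
scanSequence <- function(seq, matrix, threshold = 0, seqname = "seq") {
  stopifnot(is(matrix, "ScoringMatrix"), length(seq) == 1)
  w <- matrixWidth(matrix)
  idx <- .baseIndex(seq)
  n <- length(idx)
  if (n < w) stop("sequence shorter than the matrix width")
  sm <- scoreMatrix(matrix)
  starts <- seq_len(n - w + 1L)
  scores <- vapply(starts, function(s) {
    b <- idx[s:(s + w - 1L)]
    if (anyNA(b)) return(-Inf)
    sum(sm[cbind(b, seq_len(w))])
  }, numeric(1))
  keep <- which(scores >= threshold)
  rna <- asRna(toupper(asDna(seq)))
  if (length(keep) == 0)
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), kmer = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  data.frame(seqname = seqname, start = starts[keep],
             end = starts[keep] + w - 1L,
             kmer = substring(rna, starts[keep], starts[keep] + w - 1L),
             score = scores[keep], stringsAsFactors = FALSE)
}

#' Score the effect of a sequence variant on motif strength
#'
#' The delta (alt minus ref) of the best-scoring matrix window overlapping
#' the variant position; negative values predict disrupted binding. The
#' reference base(s) must match the sequence.
#'
#' @param seq the reference sequence (RNA or DNA spelling).
#' @param position 1-based position of the first changed base.
#' @param ref,alt reference and alternate bases (equal length,
#'   substitutions only).
#' @param matrix a \code{ScoringMatrix}.
#' @return list: \code{delta}, \code{ref_score}, \code{alt_score} (best
#'   overlapping window scores; \code{-Inf} if no window overlaps).
#' @export
variantEffect <- function(seq, position, ref, alt, matrix) {
  stopifnot(is(matrix, "ScoringMatrix"))
  ref <- toupper(asDna(ref)); alt <- toupper(asDna(alt))
  if (nchar(ref) != nchar(alt))
    stop("ref and alt must have equal length (substitutions only)")
  s <- toupper(asDna(seq))
  have <- substr(s, position, position + nchar(ref) - 1L)
  if (have != ref)
    stop(sprintf("reference mismatch at position %d: sequence has %s, not %s",
                 position, have, ref))
  altSeq <- paste0(substr(s, 1, position - 1L), alt,
                   substring(s, position + nchar(ref)))
  w <- matrixWidth(matrix)
  bestOverlap <- function(x) {
    hits <- scanSequence(x, matrix, threshold = -Inf)
    span <- c(position, position + nchar(ref) - 1L)
    ov <- hits$end >= span[1] & hits$start <= span[2]
    if (!any(ov)) return(-Inf)
    max(hits$score[ov])
  }
  refScore <- bestOverlap(s)
  altScore <- bestOverlap(altSeq)
  list(delta = altScore - refScore, ref_score = refScore,
       alt_score = altScore)
}

#' Extract peak sequences from the genome
#'
#' Sense-strand sequences of the given intervals (reverse-complemented for
#' minus-strand intervals), for motif analysis.
#'
#' @param intervals \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @return character vector of sequences (DNA alphabet, 5' to 3' in
#'   transcript orientation).
#' @export
extractSenseSequences <- function(intervals, genome) {
  vapply(seq_along(intervals), function(i) {
    s <- Biostrings::subseq(genome[[as.character(seqnames(intervals))[i]]],
                            start(intervals)[i], end(intervals)[i])
    if (as.character(strand(intervals))[i] == "-")
      s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
}
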