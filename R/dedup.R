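# Aligned-tag processing: removal of non-unique alignments, mismatch-tolerant
# PCR-duplicate collapsing on (position, random tag), single-nucleotide
# crosslink assignment, and the read-start concordance diagnostic.

#' Remove non-uniquely aligned tags
#'
#' @param tags \code{GRanges} of aligned tags (needs \code{multi_mapping}).
#' @return \code{tags} with all multi-mapping records removed, order
#'   preserved.
#' @export
filterUnique <- function(tags) {
  tags[!tags$multi_mapping]
}

# 5' start in transcript orientation: genomic start on +, genomic end on -
.fivePrime <- function(tags) {
  ifelse(as.character(strand(tags)) == "-", end(tags), start(tags))
}

# cluster a tag group by connected components of the Hamming<=1 graph;
# greedy = non-transitive single-pass alternative
.clusterTags <- function(tagStrings, greedy = FALSE) {
  n <- length(tagStrings)
  if (n == 1) return(1L)
  m <- .charMatrix(tagStrings)
  D <- matrix(0L, n, n)
  for (j in seq_len(ncol(m)))
    D <- D + outer(m[, j], m[, j], "!=")
  if (!greedy) {
    adj <- (D <= 1L) * 1L
    diag(adj) <- 0L
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    as.integer(igraph::components(g)$membership)
  } else {
    # greedy: assign each tag (in lexicographic order) to the first existing
    # cluster whose seed is within distance 1
    ord <- order(tagStrings, seq_len(n))
    comp <- integer(n); seeds <- integer(0)
    for (i in ord) {
      hit <- seeds[which(D[i, seeds] <= 1L)[1]]
      if (is.na(hit) || length(hit) == 0) {
        seeds <- c(seeds, i); comp[i] <- length(seeds)
      } else comp[i] <- comp[hit]
    }
    comp
  }
}

#' Collapse PCR duplicates using positions and random tags
#'
#' Tags are grouped by (chromosome, strand, 5' alignment start in transcript
#' orientation, sample); within a group, tags whose 5-nt random tags differ
#' by at most one mismatch are considered the same molecule. By default
#' "considered identical" is closed transitively (connected components of the
#' Hamming-distance-<=1 graph); \code{greedy = TRUE} gives the non-transitive
#' single-pass alternative. One representative per molecule is retained: the
#' record with the lexicographically smallest tag, earliest record on ties.
#'
#' @param tags \code{GRanges} of unique aligned tags (metadata
#'   \code{random_tag}, \code{sample_id}).
#' @param greedy use greedy non-transitive clustering.
#' @return list: \code{tags} (deduplicated \code{GRanges}), \code{report}
#'   (data.frame per position group: chrom, strand, position, sample,
#'   n_tags, n_molecules).
#' @export
collapsePcrDuplicates <- function(tags, greedy = FALSE) {
  if (length(tags) == 0)
    return(list(tags = tags, report = data.frame(
      chrom = character(0), strand = character(0), position = integer(0),
      sample_id = character(0), n_tags = integer(0),
      n_molecules = integer(0))))
  if (any(nchar(tags$random_tag) != 5L))
    stop("random tags must be 5 nt (found length ",
         nchar(tags$random_tag)[which(nchar(tags$random_tag) != 5L)[1]], ")")
  fp <- .fivePrime(tags)
  key <- paste(as.character(seqnames(tags)), as.character(strand(tags)),
               fp, tags$sample_id, sep = "\r")
  groups <- split(seq_along(tags), key)
  keep <- integer(0)
  rep_rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    ii <- groups[[gi]]
    comp <- .clusterTags(tags$random_tag[ii], greedy = greedy)
    byComp <- split(seq_along(ii), comp)
    reps <- vapply(byComp, function(jj) {
      o <- jj[order(tags$random_tag[ii][jj], jj)]
      ii[o[1]]
    }, integer(1))
    keep <- c(keep, reps)
    rep_rows[[gi]] <- data.frame(
      chrom = as.character(seqnames(tags))[ii[1]],
      strand = as.character(strand(tags))[ii[1]],
      position = fp[ii[1]], sample_id = tags$sample_id[ii[1]],
      n_tags = length(ii), n_molecules = length(byComp),
      stringsAsFactors = FALSE)
  }
  keep <- sort(keep)
  .logStage("dedup", "in=", length(tags), " molecules=", length(keep))
  list(tags = tags[keep], report = do.call(rbind, rep_rows))
}

#' Assign crosslink sites to deduplicated tags
#'
#' For reads without deletions the crosslink is the base immediately
#' preceding the read start in transcript orientation (genomic
#' \code{start - 1} on the plus strand, \code{end + 1} on the minus strand);
#' for reads containing deletions it is the deletion site (the 5'-most
#' deletion in transcript orientation when there are several). Tags whose
#' crosslink would fall off the chromosome are skipped and counted. Sites
#' are aggregated per (chromosome, position, strand, sample) with the
#' molecule count.
#'
#' @param tags deduplicated \code{GRanges} (metadata \code{deletions},
#'   \code{sample_id}).
#' @return list: \code{sites} (width-1 \code{GRanges} with \code{count},
#'   \code{sample_id}), \code{n_skipped}.
#' @export
assignCrosslinks <- function(tags) {
  if (length(tags) == 0) {
    sites <- GRanges()
    mcols(sites) <- S4Vectors::DataFrame(count = integer(0),
                                         sample_id = character(0))
    return(list(sites = sites, n_skipped = 0L))
  }
  minus <- as.character(strand(tags)) == "-"
  nDel <- lengths(tags$deletions)
  pos <- ifelse(minus, end(tags) + 1L, start(tags) - 1L)
  hasDel <- nDel > 0
  if (any(hasDel)) {
    delPos <- vapply(which(hasDel), function(i) {
      d <- tags$deletions[[i]]
      if (minus[i]) max(d) else min(d)
    }, integer(1))
    pos[hasDel] <- delPos
  }
  sl <- seqlengths(tags)[as.character(seqnames(tags))]
  bad <- pos < 1L | (!is.na(sl) & pos > sl)
  nSkipped <- sum(bad)
  tags <- tags[!bad]; pos <- pos[!bad]
  key <- paste(as.character(seqnames(tags)), pos,
               as.character(strand(tags)), tags$sample_id, sep = "\r")
  first <- !duplicated(key)
  cnt <- as.integer(table(key)[key[first]])
  sites <- GRanges(seqnames(tags)[first], IRanges(pos[first], pos[first]),
                   strand = strand(tags)[first],
                   seqinfo = seqinfo(tags))
  sites$count <- cnt
  sites$sample_id <- tags$sample_id[first]
  list(sites = sort(sites), n_skipped = nSkipped)
}

#' Read-start concordance diagnostic
#'
#' Checks that short and long aligned fragments share 5' starts, the
#' signature of genuine crosslink truncation. The genome is tiled in 300-nt
#' windows; windows with fewer than 20 fragments are excluded; in each
#' remaining window the modal 5'-start offset between the long class (41 nt,
#' +-1 nt admitted) and the short class (20-35 nt) is recorded. The global
#' verdict is \code{start-concordant} when the modal per-window offset is 0,
#' \code{insufficient data} when no window qualifies.
#'
#' @param tags deduplicated \code{GRanges} of aligned tags.
#' @param window_size window width (nt, default 300).
#' @param min_fragments minimum fragments per window (default 20).
#' @param short_range aligned-length range of the short class (default
#'   20-35 nt).
#' @param long_length aligned length of the long class (default 41 nt).
#' @param long_tol admitted deviation for the long class (default 1 nt).
#' @return list: \code{table} (per-window data.frame with chrom, window
#'   start, fragment counts per class, modal offset), \code{verdict}.
#' @export
startProfileDiagnostic <- function(tags, window_size = 300L,
                                   min_fragments = 20L,
                                   short_range = c(20L, 35L),
                                   long_length = 41L, long_tol = 1L) {
  len <- width(tags)
  fp <- .fivePrime(tags)
  win <- (fp - 1L) %/% window_size
  key <- paste(as.character(seqnames(tags)), win, sep = "\r")
  groups <- split(seq_along(tags), key)
  rows <- list()
  for (ii in groups) {
    if (length(ii) < min_fragments) next
    isShort <- len[ii] >= short_range[1] & len[ii] <= short_range[2]
    isLong <- abs(len[ii] - long_length) <= long_tol
    if (!any(isShort) || !any(isLong)) next
    off <- .modal(fp[ii][isLong]) - .modal(fp[ii][isShort])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(tags))[ii[1]],
      window_start = win[ii[1]] * window_size + 1L,
      n_fragments = length(ii), n_short = sum(isShort),
      n_long = sum(isLong), modal_offset = off)
  }
  if (length(rows) == 0)
    return(list(table = data.frame(), verdict = "insufficient data"))
  tab <- do.call(rbind, rows)
  verdict <- if (.modal(tab$modal_offset) == 0) "start-concordant"
             else "start-discordant"
  list(table = tab, verdict = verdict)
}
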