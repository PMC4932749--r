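# Cassette-exon splicing quantification from junction counts: replicate-mean
# PSI per condition, the pseudoinclusion log2 fold change, a pooled Fisher
# exact test with BH adjustment, regulation classes, and the splice-site
# strength / GC-content group comparisons (Wilcoxon rank-sum vs neutral).

#' Percent spliced in
#'
#' \code{inclusion / (inclusion + exclusion)}; \code{NA} (unquantifiable)
#' when both counts are zero.
#'
#' @param inclusion,exclusion junction read counts (vectorised).
#' @return numeric PSI in [0, 1], \code{NA} where unquantifiable.
#' @export
computePsi <- function(inclusion, exclusion) {
  tot <- inclusion + exclusion
  ifelse(tot > 0, inclusion / tot, NA_real_)
}

#' Compare cassette-exon inclusion between conditions
#'
#' Per exon: condition PSI is the mean of quantifiable replicate PSIs;
#' \code{delta_psi = psi_knockdown - psi_control};
#' \code{log2fc = log2((psi_kd + 0.01) / (psi_ctrl + 0.01))} (1%
#' pseudoinclusion added to each condition); the p-value is a two-sided
#' Fisher exact test on the pooled inclusion/exclusion counts of the two
#' conditions. Exons without a quantifiable replicate in each condition are
#' dropped and counted.
#'
#' @param counts data.frame with columns \code{gene_id}, \code{exon_id},
#'   \code{replicate}, \code{condition} (control/knockdown),
#'   \code{inclusion}, \code{exclusion} (as from
#'   \code{\link{simulateJunctionCounts}} or the junction-count TSV).
#' @return list: \code{events} (per-exon data.frame with psi_control,
#'   psi_knockdown, delta_psi, log2fc, p_value), \code{n_dropped}.
#' @export
compareConditions <- function(counts) {
  need <- c("gene_id", "exon_id", "replicate", "condition", "inclusion",
            "exclusion")
  stopifnot(all(need %in% names(counts)))
  counts$psi <- computePsi(counts$inclusion, counts$exclusion)
  rows <- list(); nDropped <- 0L
  for (ex in unique(counts$exon_id)) {
    sub <- counts[counts$exon_id == ex, , drop = FALSE]
    ctrl <- sub[sub$condition == "control", , drop = FALSE]
    kd <- sub[sub$condition == "knockdown", , drop = FALSE]
    pc <- mean(ctrl$psi, na.rm = TRUE)
    pk <- mean(kd$psi, na.rm = TRUE)
    if (!is.finite(pc) || !is.finite(pk)) { nDropped <- nDropped + 1L; next }
    tab <- matrix(c(sum(ctrl$inclusion), sum(ctrl$exclusion),
                    sum(kd$inclusion), sum(kd$exclusion)), nrow = 2)
    p <- fisher.test(tab)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sub$gene_id[1], exon_id = ex,
      psi_control = pc, psi_knockdown = pk, delta_psi = pk - pc,
      log2fc = log2((pk + 0.01) / (pc + 0.01)),
      p_value = p, stringsAsFactors = FALSE)
  }
  events <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(0), exon_id = character(0),
               psi_control = numeric(0), psi_knockdown = numeric(0),
               delta_psi = numeric(0), log2fc = numeric(0),
               p_value = numeric(0))
  list(events = events, n_dropped = nDropped)
}

#' Classify events as activated, repressed or neutral
#'
#' P-values are BH-adjusted across all tested events; significant events
#' (\code{fdr < fdr_threshold}) with inclusion up on knockdown are
#' \code{repressed} by the factor (the knockdown relieves repression), those
#' with inclusion down are \code{activated}; everything else is
#' \code{neutral}.
#'
#' @param events data.frame from \code{\link{compareConditions}}.
#' @param fdr_threshold significance threshold (default 0.1).
#' @return \code{events} with added \code{fdr} and \code{regulation_class}.
#' @export
classifyEvents <- function(events, fdr_threshold = 0.1) {
  events$fdr <- p.adjust(events$p_value, method = "BH")
  sig <- events$fdr < fdr_threshold
  events$regulation_class <- ifelse(sig & events$delta_psi > 0, "repressed",
                             ifelse(sig & events$delta_psi < 0, "activated",
                                    "neutral"))
  events
}

#' Train a first-order PWM splice-site scorer from annotation
#'
#' Builds log2 scoring matrices over annotated donor (last 3 exonic + first
#' 6 intronic nt) or acceptor (last 20 intronic + first 3 exonic nt)
#' windows. This built-in scorer exercises the strength-comparison machinery;
#' an external scorer (e.g. a maximum-entropy model) can be plugged into
#' \code{\link{spliceSiteStrengthCompare}} instead.
#'
#' @param genome \code{DNAStringSet}.
#' @param annotation a \code{GenomeAnnotation}.
#' @param site \code{"donor"} or \code{"acceptor"}.
#' @return a function mapping a window sequence to a score in bits, with
#'   attribute \code{window} = c(exonic, intronic) nt.
#' @export
trainSpliceSitePwm <- function(genome, annotation, site = c("donor",
                                                            "acceptor")) {
  site <- match.arg(site)
  win <- spliceSiteWindows(annotation, site)
  seqs <- extractSenseSequences(win, genome)
  fm <- buildFrequencyMatrix(seqs)
  sm <- buildScoringMatrix(fm)
  f <- function(seq) {
    idx <- .baseIndex(seq)
    w <- matrixWidth(sm)
    if (length(idx) != w) stop("window must be ", w, " nt")
    sum(scoreMatrix(sm)[cbind(idx, seq_len(w))])
  }
  attr(f, "matrix") <- sm
  attr(f, "window") <- if (site == "donor") c(3L, 6L) else c(3L, 20L)
  f
}

#' Splice-site windows of annotated internal exons
#'
#' Donor: last 3 exonic + first 6 intronic nt at the exon 3' boundary;
#' acceptor: last 20 intronic + first 3 exonic nt at the 5' boundary; in
#' transcript orientation.
#'
#' @param annotation a \code{GenomeAnnotation}.
#' @param site \code{"donor"} or \code{"acceptor"}.
#' @param exons optional \code{GRanges} of exons (default: all internal
#'   exons with the needed flanking intron).
#' @return \code{GRanges} of windows.
#' @export
spliceSiteWindows <- function(annotation, site = c("donor", "acceptor"),
                              exons = NULL) {
  site <- match.arg(site)
  if (is.null(exons)) {
    ex <- annExons(annotation)
    exons <- ex[grepl("internal", ex$exon_class)]
  }
  minus <- as.character(strand(exons)) == "-"
  if (site == "donor") {
    s <- ifelse(minus, start(exons) - 6L, end(exons) - 2L)
    e <- ifelse(minus, start(exons) + 2L, end(exons) + 6L)
  } else {
    s <- ifelse(minus, end(exons) - 2L, start(exons) - 20L)
    e <- ifelse(minus, end(exons) + 20L, start(exons) + 2L)
  }
  GRanges(seqnames(exons), IRanges(s, e), strand = strand(exons),
          seqinfo = seqinfo(exons))
}

#' Compare splice-site strength between regulation classes
#'
#' Two-sided Wilcoxon rank-sum tests of each regulated group (activated,
#' repressed) against the neutral group, per site type, using the supplied
#' scorer. Groups with fewer than 3 members are skipped with a warning.
#'
#' @param scores named list of numeric score vectors:
#'   \code{activated}, \code{repressed}, \code{neutral}.
#' @return data.frame: \code{group}, \code{n}, \code{n_neutral},
#'   \code{median}, \code{median_neutral}, \code{p_value} (NA when skipped).
#' @export
spliceSiteStrengthCompare <- function(scores) {
  stopifnot("neutral" %in% names(scores))
  neutral <- scores$neutral
  rows <- list()
  for (g in setdiff(names(scores), "neutral")) {
    x <- scores[[g]]
    if (length(x) < 3 || length(neutral) < 3) {
      warning("group '", g, "' skipped: fewer than 3 members")
      p <- NA_real_
    } else {
      p <- wilcox.test(x, neutral, alternative = "two.sided")$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, n = length(x), n_neutral = length(neutral),
      median = if (length(x)) stats::median(x) else NA_real_,
      median_neutral = stats::median(neutral), p_value = p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Score splice sites of a set of exons
#'
#' @param genome \code{DNAStringSet}.
#' @param annotation a \code{GenomeAnnotation}.
#' @param exons \code{GRanges} of exons.
#' @param scorer function from \code{\link{trainSpliceSitePwm}} (or an
#'   external drop-in with the same interface).
#' @param site \code{"donor"} or \code{"acceptor"}.
#' @return numeric scores, one per exon.
#' @export
scoreSpliceSites <- function(genome, annotation, exons, scorer,
                             site = c("donor", "acceptor")) {
  site <- match.arg(site)
  win <- spliceSiteWindows(annotation, site, exons = exons)
  vapply(extractSenseSequences(win, genome), scorer, numeric(1),
         USE.NAMES = FALSE)
}

#' GC content of regulated exons and their flanks
#'
#' GC fraction of each exon and of its 100-nt upstream and downstream
#' flanks (clipped and flagged at contig edges), with two-sided Wilcoxon
#' rank-sum comparisons of each regulated group against neutral, per region.
#'
#' @param genome \code{DNAStringSet}.
#' @param exons \code{GRanges} with a \code{regulation_class} metadata
#'   column.
#' @param flank flank width (nt, default 100).
#' @return list: \code{per_exon} (data.frame of GC fractions),
#'   \code{comparisons} (data.frame group x region with p-values).
#' @export
gcContentCompare <- function(genome, exons, flank = 100L) {
  stopifnot(!is.null(exons$regulation_class))
  lens <- setNames(Biostrings::nchar(genome), names(genome))
  gc <- function(gr) {
    vapply(seq_along(gr), function(i) {
      s <- Biostrings::subseq(genome[[as.character(seqnames(gr))[i]]],
                              start(gr)[i], end(gr)[i])
      as.numeric(Biostrings::letterFrequency(s, "GC", as.prob = TRUE))
    }, numeric(1))
  }
  minus <- as.character(strand(exons)) == "-"
  upS <- ifelse(minus, end(exons) + 1L, start(exons) - flank)
  upE <- ifelse(minus, end(exons) + flank, start(exons) - 1L)
  dnS <- ifelse(minus, start(exons) - flank, end(exons) + 1L)
  dnE <- ifelse(minus, start(exons) - 1L, end(exons) + flank)
  maxLen <- lens[as.character(seqnames(exons))]
  clipped <- upS < 1 | dnS < 1 | upE > maxLen | dnE > maxLen
  up <- GRanges(seqnames(exons),
                IRanges(pmax(upS, 1L), pmin(upE, maxLen)))
  dn <- GRanges(seqnames(exons),
                IRanges(pmax(dnS, 1L), pmin(dnE, maxLen)))
  perExon <- data.frame(
    exon_id = if (!is.null(exons$exon_id)) exons$exon_id
              else as.character(seq_along(exons)),
    regulation_class = exons$regulation_class,
    gc_exon = gc(exons), gc_upstream = gc(up), gc_downstream = gc(dn),
    flank_clipped = clipped, stringsAsFactors = FALSE)
  comps <- list()
  for (g in setdiff(unique(perExon$regulation_class), "neutral")) {
    for (reg in c("gc_exon", "gc_upstream", "gc_downstream")) {
      x <- perExon[[reg]][perExon$regulation_class == g]
      y <- perExon[[reg]][perExon$regulation_class == "neutral"]
      p <- if (length(x) >= 3 && length(y) >= 3)
        wilcox.test(x, y)$p.value else NA_real_
      comps[[length(comps) + 1L]] <- data.frame(
        group = g, region = reg, n = length(x), p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  list(per_exon = perExon,
       comparisons = if (length(comps)) do.call(rbind, comps)
                     else data.frame())
}
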