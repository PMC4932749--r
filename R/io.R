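# Readers and writers for the formats the pipeline touches. Standard formats
# go through Biostrings / rtracklayer; SAM-lite (the M/D/I text subset used to
# carry aligned tags) has its own strict parser. All readers reject malformed
# records rather than repairing them.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named \code{DNAStringSet}, sequences uppercased, names unique.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  isSeq <- !startsWith(ln, ">") & nzchar(ln)
  badLine <- which(isSeq &
                     !grepl("^[ACGTUMRWSYKVHDBNacgtumrwsykvhdbn.-]*$", ln))
  if (length(badLine) > 0)
    stop("malformed FASTA in ", path, ": non-IUPAC characters at line ",
         badLine[1])
  if (length(ln) > 0 && !startsWith(ln[1], ">"))
    stop("malformed FASTA in ", path, ": missing header at line 1")
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0) stop("FASTA contains no records: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence name in FASTA: ",
         names(x)[duplicated(names(x))][1])
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Read / write FASTQ as a plain read table
#'
#' Reads are handled as a data.frame with columns \code{name}, \code{seq},
#' \code{qual} (Sanger-encoded quality string), the form the preprocessing
#' stage operates on.
#'
#' @param path FASTQ file.
#' @return data.frame with columns \code{name}, \code{seq}, \code{qual}.
#' @export
readFastq <- function(path) {
  # the quality-scaled constructor warns about dropping the quality mcols it
  # reads itself; harmless
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  out <- data.frame(name = names(x),
                    seq = unname(as.character(x)),
                    qual = unname(as.character(Biostrings::quality(x))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname readFastq
#' @param reads data.frame with \code{name}, \code{seq}, \code{qual}.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(all(c("name", "seq", "qual") %in% names(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$name
  suppressWarnings(
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::quality(x)))
  invisible(path)
}

#' Construct a GenomeAnnotation, classifying exons
#'
#' Assigns exon ranks (5' to 3' in transcript orientation) and exon class
#' labels: \code{first}, \code{last}, \code{internal}, plus \code{cassette}
#' for internal exons absent from at least one other transcript of the same
#' gene. A single-exon transcript's exon is both \code{first} and \code{last}.
#'
#' @param genes \code{GRanges} named by gene id.
#' @param transcripts \code{GRanges} named by transcript id with metadata
#'   column \code{gene_id}.
#' @param exons \code{GRanges} with metadata column \code{transcript_id}.
#' @param cds optional \code{GRanges} of coding regions.
#' @return a \code{GenomeAnnotation}.
#' @export
makeGenomeAnnotation <- function(genes, transcripts, exons,
                                 cds = GRanges()) {
  if (is.null(exons$transcript_id))
    stop("exons must carry a transcript_id metadata column")
  txGene <- setNames(transcripts$gene_id, names(transcripts))
  exons$gene_id <- unname(txGene[exons$transcript_id])
  # rank 5'->3' within transcript
  exons$exon_rank <- NA_integer_
  byTx <- split(seq_along(exons), exons$transcript_id)
  for (ii in byTx) {
    minus <- as.character(strand(exons))[ii[1]] == "-"
    o <- order(start(exons)[ii], decreasing = minus)
    exons$exon_rank[ii[o]] <- seq_along(ii)
  }
  nExonTx <- unname(lengths(byTx)[exons$transcript_id])
  cls <- ifelse(exons$exon_rank == 1 & nExonTx == 1, "first,last",
         ifelse(exons$exon_rank == 1, "first",
         ifelse(exons$exon_rank == nExonTx, "last", "internal")))
  # cassette: internal exon absent from >= 1 other transcript of its gene
  internal <- cls == "internal"
  if (any(internal)) {
    key <- paste(as.character(seqnames(exons)), start(exons), end(exons))
    for (g in unique(exons$gene_id[internal])) {
      gi <- which(exons$gene_id == g)
      txs <- unique(exons$transcript_id[gi])
      if (length(txs) < 2) next
      for (i in gi[internal[gi]]) {
        present <- vapply(txs, function(t)
          key[i] %in% key[gi][exons$transcript_id[gi] == t], logical(1))
        if (!all(present)) cls[i] <- "internal,cassette"
      }
    }
  }
  exons$exon_class <- cls
  methods::new("GenomeAnnotation", genes = genes, transcripts = transcripts,
               exons = exons, cds = cds)
}

#' Read a GTF annotation
#'
#' Expects gene/transcript/exon (optionally CDS) features with 1-based
#' inclusive coordinates; converted to \code{GRanges} and exons classified as
#' in \code{\link{makeGenomeAnnotation}}. Cassette status is derived from the
#' annotation (an internal exon skipped by a sibling transcript); it can also
#' be imposed afterwards with \code{\link{markCassetteExons}} when it comes
#' from RNA-seq rather than annotation.
#'
#' @param path GTF file.
#' @return a \code{GenomeAnnotation}.
#' @export
readGtfAnnotation <- function(path) {
  g <- tryCatch(rtracklayer::import(path, format = "gtf"),
                error = function(e) stop("malformed GTF in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  type <- as.character(g$type)
  tx <- g[type == "transcript"]
  names(tx) <- tx$transcript_id
  genes <- g[type == "gene"]
  if (length(genes) == 0) {
    # derive gene spans from transcripts
    spl <- split(tx, tx$gene_id)
    genes <- unlist(range(spl))
  } else {
    names(genes) <- genes$gene_id
    genes <- granges(genes)
  }
  ex <- g[type == "exon"]
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    transcript_id = ex$transcript_id)
  cds <- g[type == "CDS"]
  if (length(cds) > 0)
    S4Vectors::mcols(cds) <- S4Vectors::DataFrame(
      transcript_id = cds$transcript_id)
  mcols(tx) <- S4Vectors::DataFrame(gene_id = tx$gene_id)
  makeGenomeAnnotation(genes = genes, transcripts = tx, exons = ex,
                       cds = granges(cds, use.mcols = TRUE))
}

#' Impose cassette status on annotated exons
#'
#' Marks the exon records matching the supplied intervals as cassette exons
#' (they must be internal). Used when cassette exons are defined by RNA-seq
#' evidence supplied as a side table rather than by the annotation.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param intervals \code{GRanges} of cassette-exon coordinates.
#' @return the updated \code{GenomeAnnotation}.
#' @export
markCassetteExons <- function(ann, intervals) {
  ex <- ann@exons
  hit <- findOverlaps(ex, intervals, type = "equal")
  idx <- unique(S4Vectors::queryHits(hit))
  bad <- idx[!grepl("internal", ex$exon_class[idx])]
  if (length(bad) > 0)
    stop("cassette exons must be internal exons; offending exon in ",
         ex$transcript_id[bad[1]])
  add <- idx[!grepl("cassette", ex$exon_class[idx])]
  ex$exon_class[add] <- paste0(ex$exon_class[add], ",cassette")
  methods::initialize(ann, exons = ex)
}

#' Read / write BED6 intervals
#'
#' BED is 0-based half-open on disk; in memory intervals are 1-based closed
#' \code{GRanges} with \code{name} and \code{score} metadata columns, so
#' \code{readBed(writeBed(x))} is the identity.
#'
#' @param path BED file.
#' @return \code{GRanges} with \code{name} and \code{score}.
#' @export
readBed <- function(path) {
  x <- tryCatch(rtracklayer::import(path, format = "bed"),
                error = function(e) stop("malformed BED in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (any(width(x) < 1)) stop("malformed BED in ", path, ": empty interval")
  x
}

#' @rdname readBed
#' @param x \code{GRanges} (metadata columns \code{name}, \code{score} used
#'   if present).
#' @export
writeBed <- function(x, path) {
  if (is.null(x$score)) x$score <- 0L
  if (is.null(x$name)) x$name <- paste0("iv", seq_along(x))
  rtracklayer::export(x, path, format = "bed")
  invisible(path)
}

# ---- SAM-lite -------------------------------------------------------------

.CIGAR_RE <- "^([0-9]+[MDI])+$"

# walk a CIGAR string; returns list(span, deletions) relative to POS
.cigarWalk <- function(cigar) {
  if (!grepl(.CIGAR_RE, cigar))
    stop("unsupported CIGAR operation in '", cigar,
         "' (only M, D, I are supported)")
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MDI]", cigar))[[1]]
  pos <- 0L
  dels <- integer(0)
  for (i in seq_along(ops)) {
    if (ops[i] == "M") {
      pos <- pos + lens[i]
    } else if (ops[i] == "D") {
      dels <- c(dels, pos + seq_len(lens[i]))
      pos <- pos + lens[i]
    } # I consumes read only
  }
  list(span = pos, deletions = dels)
}

#' Read aligned tags from a SAM-lite file
#'
#' Parses the plain-text SAM subset used for aligned iCLIP tags: header lines
#' (\code{@...}) are skipped; each record needs QNAME, FLAG (0/16 for
#' strand), RNAME, POS (1-based), MAPQ and a CIGAR over M/D/I. The 5-nt
#' random tag travels as a \code{#TAG} suffix on the read name. Deletion
#' genomic positions are extracted from D operations; reads whose name occurs
#' in more than one record are flagged multi-mapping.
#'
#' @param path SAM-lite file.
#' @param sample_id sample label attached to every tag (alignment happens on
#'   demultiplexed per-sample files).
#' @return \code{GRanges} of aligned tags with metadata columns \code{name},
#'   \code{random_tag}, \code{deletions} (\code{IntegerList} of genomic
#'   positions), \code{multi_mapping}, \code{sample_id}.
#' @export
readSamLite <- function(path, sample_id = "s1") {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@") & nzchar(ln)]
  if (length(ln) == 0) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(
      name = character(0), random_tag = character(0),
      deletions = IRanges::IntegerList(), multi_mapping = logical(0),
      sample_id = character(0))
    return(gr)
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6))
    stop("malformed SAM-lite record at line ", which(nf < 6)[1])
  qname <- vapply(f, `[`, character(1), 1)
  flag <- as.integer(vapply(f, `[`, character(1), 2))
  rname <- vapply(f, `[`, character(1), 3)
  pos <- as.integer(vapply(f, `[`, character(1), 4))
  cigar <- vapply(f, `[`, character(1), 6)
  if (anyNA(flag) || anyNA(pos))
    stop("malformed SAM-lite record: non-numeric FLAG or POS")
  walks <- lapply(cigar, .cigarWalk)
  span <- vapply(walks, `[[`, integer(1), "span")
  dels <- IRanges::IntegerList(lapply(seq_along(walks), function(i)
    pos[i] - 1L + walks[[i]]$deletions))
  tag <- ifelse(grepl("#", qname, fixed = TRUE),
                sub("^.*#", "", qname), NA_character_)
  gr <- GRanges(rname, IRanges(pos, pos + span - 1L),
                strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"))
  gr$name <- qname
  gr$random_tag <- tag
  gr$deletions <- dels
  gr$multi_mapping <- qname %in% qname[duplicated(qname)]
  gr$sample_id <- sample_id
  gr
}

#' @rdname readSamLite
#' @param tags \code{GRanges} of aligned tags with a \code{cigar} metadata
#'   column (as written by the simulator) or plain matches.
#' @param seqlengths named vector of chromosome lengths for the header.
#' @export
writeSamLite <- function(tags, path, seqlengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seqlengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                       as.integer(seqlengths)), con)
  cig <- if (!is.null(tags$cigar)) tags$cigar else paste0(width(tags), "M")
  flag <- ifelse(as.character(strand(tags)) == "-", 16L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t37\t%s\t*\t0\t0\t*\t*",
                     tags$name, flag, as.character(seqnames(tags)),
                     start(tags), cig), con)
  invisible(path)
}

#' Write a GenomeAnnotation as GTF
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param path output GTF file.
#' @export
writeGtfAnnotation <- function(ann, path) {
  gn <- annGenes(ann); tx <- annTranscripts(ann); ex <- annExons(ann)
  cds <- annCds(ann)
  gn2 <- granges(gn); gn2$type <- "gene"; gn2$gene_id <- names(gn)
  gn2$transcript_id <- NA_character_
  tx2 <- granges(tx); tx2$type <- "transcript"; tx2$gene_id <- tx$gene_id
  tx2$transcript_id <- names(tx)
  ex2 <- granges(ex); ex2$type <- "exon"; ex2$gene_id <- ex$gene_id
  ex2$transcript_id <- ex$transcript_id
  all <- c(gn2, tx2, ex2)
  if (length(cds) > 0) {
    cd2 <- granges(cds); cd2$type <- "CDS"
    cd2$transcript_id <- cds$transcript_id
    cd2$gene_id <- setNames(tx$gene_id, names(tx))[cds$transcript_id]
    all <- c(all, cd2)
  }
  all$source <- "iCLIPkit"
  suppressWarnings(rtracklayer::export(all, path, format = "gtf"))
  invisible(path)
}
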