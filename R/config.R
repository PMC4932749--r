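#' Pipeline configuration
#'
#' Bundles the analysis parameters used across the pipeline stages. Defaults
#' are the standard protocol values: barcode scheme \code{RRRIIIIRR} (5 random
#' positions forming the PCR tag, 4 identifier positions), minimum read length
#' 20 nt after trimming, crosslink regions of +-10 nt, peak FDR threshold
#' 0.10 with a 1-kb superlocal background window, k-mer lengths 6/7/8 for
#' motif enrichment, a flat 0.25 background base frequency for motif scoring,
#' and an SSO target window 10-40 nt downstream of the 5' splice site.
#'
#' @param barcode_scheme string over \code{R} (random) and \code{I}
#'   (identifier) giving the 5' barcode layout.
#' @param adapter 3' sequencing adapter (DNA).
#' @param min_read_length minimum retained read length (nt) after trimming.
#' @param crosslink_flank nt added to each side of a crosslink site to form
#'   its binding region.
#' @param peak_fdr Benjamini-Hochberg FDR threshold for significant peaks.
#' @param n_permutations permutations per candidate for the peak null.
#' @param superlocal_window total width (nt) of the local background window
#'   around a candidate peak.
#' @param kmer_lengths k-mer lengths for motif enrichment.
#' @param background_base_freq flat background base frequency for the
#'   scoring matrix.
#' @param sso_window integer pair: accepted distance range (nt, inclusive)
#'   from the first intronic base downstream of a donor site to the nearest
#'   peak edge.
#' @param quality_threshold Phred threshold for 3' running-sum quality
#'   trimming.
#' @param adapter_max_mismatch mismatches allowed in adapter matching.
#' @param adapter_min_overlap minimum 3'-terminal adapter overlap (nt).
#' @param seed integer seed used for all stochastic stages.
#' @return a validated list of class \code{PipelineConfig}.
#' @export
#' @examples
#' cfg <- pipelineConfig()
#' cfg$peak_fdr
pipelineConfig <- function(barcode_scheme = "RRRIIIIRR",
                           adapter = "AGATCGGAAGAGC",
                           min_read_length = 20L,
                           crosslink_flank = 10L,
                           peak_fdr = 0.10,
                           n_permutations = 1000L,
                           superlocal_window = 1000L,
                           kmer_lengths = c(6L, 7L, 8L),
                           background_base_freq = 0.25,
                           sso_window = c(10L, 40L),
                           quality_threshold = 20L,
                           adapter_max_mismatch = 1L,
                           adapter_min_overlap = 3L,
                           seed = 1L) {
  cfg <- list(
    barcode_scheme = barcode_scheme, adapter = adapter,
    min_read_length = as.integer(min_read_length),
    crosslink_flank = as.integer(crosslink_flank),
    peak_fdr = peak_fdr, n_permutations = as.integer(n_permutations),
    superlocal_window = as.integer(superlocal_window),
    kmer_lengths = as.integer(kmer_lengths),
    background_base_freq = background_base_freq,
    sso_window = as.integer(sso_window),
    quality_threshold = as.integer(quality_threshold),
    adapter_max_mismatch = as.integer(adapter_max_mismatch),
    adapter_min_overlap = as.integer(adapter_min_overlap),
    seed = as.integer(seed))
  if (!grepl("^[RI]+$", cfg$barcode_scheme))
    stop("barcode_scheme must be a string over {R, I}")
  if (cfg$peak_fdr <= 0 || cfg$peak_fdr > 1)
    stop("peak_fdr must be in (0, 1]")
  if (cfg$background_base_freq <= 0 || cfg$background_base_freq >= 1)
    stop("background_base_freq must be in (0, 1)")
  if (length(cfg$sso_window) != 2 || cfg$sso_window[1] > cfg$sso_window[2])
    stop("sso_window must be an ordered (min, max) pair")
  if (cfg$min_read_length < 1) stop("min_read_length must be positive")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Synthetic-data generator configuration
#'
#' Conditions for the toy genome, iCLIP read and junction-count simulators.
#' Background sequence is i.i.d. uniform over ACGT (0.25 each base); the
#' binding motif (default \code{UAGGGA}, the canonical hnRNP A1 consensus) is
#' implanted at true crosslink sites at \code{motif_implant_rate}. Reads
#' truncate at the crosslink with probability \code{truncation_fraction};
#' otherwise they read through, leaving a 1-2 nt deletion at the site. Each
#' cDNA molecule is sequenced \code{1 + Poisson(pcr_duplication_mean)} times,
#' with per-base substitution errors on the 5-nt random tag at
#' \code{tag_error_rate}. Cassette-exon junction counts are Binomial at
#' \code{junction_depth} around the configured per-condition inclusion levels.
#'
#' @param n_genes number of genes (strands alternate).
#' @param n_exons_range exons per gene (uniform integer range).
#' @param exon_length_range exon length range (nt).
#' @param intron_length_range intron length range (nt).
#' @param fraction_cassette fraction of genes whose middle exon is a cassette
#'   exon (skipped by a second transcript).
#' @param motif implanted binding motif (RNA or DNA spelling).
#' @param motif_implant_rate fraction of true crosslink sites carrying the
#'   motif immediately downstream.
#' @param crosslink_sites_per_gene true binding sites per gene.
#' @param molecules_per_site mean true cDNA molecules per binding site
#'   (Poisson, minimum 1).
#' @param background_per_kb mean single-molecule background crosslink events
#'   per kb of gene.
#' @param truncation_fraction probability a molecule truncates at the
#'   crosslink (vs reading through with a deletion).
#' @param pcr_duplication_mean expected PCR duplicates per molecule.
#' @param tag_error_rate per-base substitution probability on the random tag
#'   of each duplicate.
#' @param read_length_range cDNA fragment length range (nt).
#' @param adapter 3' adapter appended when the fragment is shorter than the
#'   machine read length.
#' @param sample_sheet named character vector: identifier (4-nt I segment)
#'   -> sample name.
#' @param psi_control,psi_knockdown per-cassette-exon inclusion levels
#'   (recycled); the defaults give a 0.3 inclusion shift on knockdown.
#' @param junction_depth junction reads per replicate per exon.
#' @param n_replicates replicates per condition.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_genes = 20L,
                             n_exons_range = c(3L, 5L),
                             exon_length_range = c(80L, 200L),
                             intron_length_range = c(200L, 800L),
                             fraction_cassette = 0.5,
                             motif = "UAGGGA",
                             motif_implant_rate = 0.6,
                             crosslink_sites_per_gene = 5L,
                             molecules_per_site = 20,
                             background_per_kb = 1,
                             truncation_fraction = 0.85,
                             pcr_duplication_mean = 3,
                             tag_error_rate = 0.01,
                             read_length_range = c(35L, 50L),
                             adapter = "AGATCGGAAGAGC",
                             sample_sheet = c(TTCA = "s1"),
                             psi_control = 0.5,
                             psi_knockdown = 0.8,
                             junction_depth = 100L,
                             n_replicates = 3L,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_exons_range = as.integer(n_exons_range),
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    fraction_cassette = fraction_cassette,
    motif = toupper(asDna(motif)),
    motif_implant_rate = motif_implant_rate,
    crosslink_sites_per_gene = as.integer(crosslink_sites_per_gene),
    molecules_per_site = molecules_per_site,
    background_per_kb = background_per_kb,
    truncation_fraction = truncation_fraction,
    pcr_duplication_mean = pcr_duplication_mean,
    tag_error_rate = tag_error_rate,
    read_length_range = as.integer(read_length_range),
    adapter = adapter,
    sample_sheet = sample_sheet,
    psi_control = psi_control,
    psi_knockdown = psi_knockdown,
    junction_depth = as.integer(junction_depth),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed))
  fr <- c(cfg$fraction_cassette, cfg$motif_implant_rate,
          cfg$truncation_fraction, cfg$tag_error_rate,
          cfg$psi_control, cfg$psi_knockdown)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (!grepl("^[ACGT]+$", cfg$motif)) stop("motif must be a DNA/RNA string")
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  if (any(cfg$exon_length_range < nchar(cfg$motif)))
    stop("exons must be at least as long as the motif")
  if (cfg$intron_length_range[1] < 50)
    stop("introns shorter than 50 nt are not supported by the generator")
  if (any(diff(cfg$read_length_range) < 0) ||
      any(diff(cfg$exon_length_range) < 0) ||
      any(diff(cfg$intron_length_range) < 0) ||
      any(diff(cfg$n_exons_range) < 0))
    stop("ranges must be ordered (min, max)")
  if (cfg$read_length_range[1] < 20)
    stop("read lengths must cover the minimum retained read length")
  class(cfg) <- "SimulationConfig"
  cfg
}
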