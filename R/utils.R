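# Small shared helpers. Sequences are handled as DNA internally (T); user-facing
# motif output uses the RNA alphabet (U). Conversion is a pure relabelling.

#' Convert between DNA and RNA spelling
#'
#' Pure relabelling of T and U (both cases); no complementing.
#'
#' @param x character vector of sequences.
#' @return character vector.
#' @export
#' @examples
#' asRna("TAGGGA")  # "UAGGGA"
#' asDna("UAGGGA")  # "TAGGGA"
asRna <- function(x) chartr("Tt", "Uu", x)

#' @rdname asRna
#' @export
asDna <- function(x) chartr("Uu", "Tt", x)

#' Reverse complement to the RNA alphabet
#'
#' The antisense sequence, 5' to 3', spelled as RNA -- the form in which an
#' SSO sequence is written.
#'
#' @param x character scalar or vector, DNA or RNA spelling.
#' @return character vector of RNA reverse complements.
#' @export
reverseComplementRna <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::RNAString(
      Biostrings::reverseComplement(Biostrings::DNAString(asDna(s)))))
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between equal-length strings (vectorised over pairs)
.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

# Most frequent value; ties broken by the smallest value
.modal <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

# n x k character matrix from equal-length strings
.charMatrix <- function(x) {
  do.call(rbind, strsplit(x, "", fixed = TRUE))
}

# stage logging to stderr
.logStage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# derive a stream seed below 2^31 from a base seed and a stream index
.streamSeed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 7919L) %% 2147483629L
}
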