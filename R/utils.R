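#' @keywords internal
"_PACKAGE"

#' @importFrom stats pbinom rbinom runif setNames cor p.adjust binom.test ks.test
#' @importFrom utils adist read.table write.table
NULL

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the package; the
#' alphabet is restricted to A/C/G/T/N (U is mapped to T at input time).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Round half away from zero (R's round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Normalize raw sequence text to the internal alphabet.
normalize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N,U}: ",
         paste(utils::head(names(x)[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  x
}

# Periodic (circular) subsequence: 0-based start, any length; the sequence
# wraps as many times as needed.
periodic_substr <- function(s, start, len) {
  L <- nchar(s)
  stopifnot(L >= 1L, len >= 0L)
  if (len == 0L) return("")
  reps <- ceiling((start %% L + len) / L) + 1L
  big <- strrep(s, reps)
  substr(big, (start %% L) + 1L, (start %% L) + len)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

CODON_STOP <- c("TAA", "TAG", "TGA")

#' Translate a DNA sequence
#'
#' Standard genetic code, reading frame 0; trailing partial codons are
#' dropped. Stops render as `*`.
#'
#' @param dna character scalar, A/C/G/T.
#' @return character scalar of amino acids.
#' @export
translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Internal condition helpers -------------------------------------------------

cl_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "circleave_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Strand-aware validity check used by several constructors.
check_interval <- function(start, end, where = "interval") {
  if (any(end <= start) || any(start < 0)) {
    cl_stop("CoordinateError", "%s: need 0 <= start < end", where)
  }
  invisible(TRUE)
}
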