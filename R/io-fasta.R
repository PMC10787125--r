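#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and U is mapped to T so that one nucleotide
#' alphabet (A/C/G/T/N) is used everywhere internally. Record order is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) cl_stop("FileNotFound", "no such file: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    cl_stop("MalformedFasta", "not a FASTA file (no '>' header): %s", path)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) cl_stop("MalformedFasta", "empty record id")
  if (any(nchar(seqs) == 0L)) {
    cl_stop("EmptySequence", "zero-length sequence: %s",
            names(seqs)[nchar(seqs) == 0L][1])
  }
  normalize_seq(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
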