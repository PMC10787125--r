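#' Build a back-splice junction reference
#'
#' For a circle with spliced sequence S of length L, the reference is the
#' last f nt of S followed by the first f nt, with f = min(50, floor(L/2)).
#' Reading across the middle of this reference therefore reproduces the
#' periodic extension of the circle across its back-splice point. The cap at
#' floor(L/2) prevents the same circle base appearing twice in one reference.
#'
#' @param circ a [circ_rna].
#' @param genome named character vector of chromosome sequences.
#' @param flank maximum flank length on each side of the junction.
#' @return list with `circ_id`, `seq` and `junction_offset` (index of the
#'   first base after the junction, equal to the upstream flank length).
#' @export
build_junction_reference <- function(circ, genome, flank = 50L) {
  S <- circ_spliced_seq(circ, genome)
  L <- nchar(S)
  f <- min(flank, L %/% 2L)
  if (f < 1L) cl_stop("SequenceUnavailable", "circle %s too short", circ$id)
  seq <- paste0(substr(S, L - f + 1L, L), substr(S, 1L, f))
  list(circ_id = circ$id, seq = seq, junction_offset = f)
}

#' Map reads across back-splice junctions
#'
#' Ungapped scan of each read against each junction reference (reads are
#' assumed sense). A hit requires at most `max_mismatch` mismatches and at
#' least `min_overhang` read bases on each side of the junction. Among
#' equally good placements the leftmost is reported.
#'
#' @param reads named character vector of read sequences.
#' @param refs list of references from [build_junction_reference()].
#' @param max_mismatch maximum mismatches per hit.
#' @param min_overhang minimum read bases on each side of the junction.
#' @return data.frame with `read_id`, `circ_id`, `start` (0-based offset in
#'   the reference), `overhang_left`, `overhang_right`, `mismatches`.
#' @export
map_junction_spanning_reads <- function(reads, refs, max_mismatch = 1L,
                                        min_overhang = 5L) {
  if (any(nchar(reads) < 2L * min_overhang)) {
    cl_stop("ReadTooShort", "reads must be >= 2*min_overhang nt")
  }
  rows <- list()
  for (ri in seq_along(reads)) {
    rseq <- reads[[ri]]
    rid <- names(reads)[ri]
    n <- nchar(rseq)
    rchars <- strsplit(rseq, "")[[1]]
    for (ref in refs) {
      m <- nchar(ref$seq)
      if (n > m) next
      jo <- ref$junction_offset
      # offsets where the read covers >= min_overhang on both junction sides
      off_lo <- max(0L, jo + min_overhang - n)
      off_hi <- jo - min_overhang
      if (off_hi < off_lo) next
      refchars <- strsplit(ref$seq, "")[[1]]
      best <- NULL
      for (off in off_lo:off_hi) {
        mm <- sum(rchars != refchars[(off + 1L):(off + n)])
        if (mm <= max_mismatch && (is.null(best) || mm < best$mm)) {
          best <- list(off = off, mm = mm)
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = rid, circ_id = ref$circ_id, start = best$off,
          overhang_left = jo - best$off,
          overhang_right = best$off + n - jo,
          mismatches = best$mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read_id = character(0), circ_id = character(0),
                      start = integer(0), overhang_left = integer(0),
                      overhang_right = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
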