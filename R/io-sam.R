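#' Read degradome alignments and locate read 5' ends
#'
#' Parses a SAM file (converted through a temporary BAM) and reports, per
#' mapped record, the 0-based position of the read's 5'-most *mapped* base:
#' the leftmost reference base for plus-strand alignments and the rightmost
#' for minus-strand alignments (soft clips excluded). Multi-mapping counts
#' come from the NH tag when present, otherwise from the number of records
#' sharing a read id. Unmapped records are skipped and counted.
#'
#' @param path SAM file with a header.
#' @param strict if `TRUE`, error when an NH tag disagrees with the observed
#'   record count for a read.
#' @return data.frame with columns `read_id`, `ref`, `start`, `end`
#'   (0-based half-open reference span), `strand`, `n_hits`, `five_prime`;
#'   attribute `n_unmapped` carries the skipped-record count.
#' @export
read_alignments_5p <- function(path, strict = FALSE) {
  if (!file.exists(path)) cl_stop("FileNotFound", "no such file: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, "@")) {
    cl_stop("MissingHeader", "SAM file lacks a header: %s", path)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
    tag = "NH")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  n_unmapped <- sum(!mapped)
  qname <- res$qname[mapped]
  pos1 <- res$pos[mapped]
  cigar <- res$cigar[mapped]
  strand <- as.character(res$strand[mapped])
  rname <- as.character(res$rname[mapped])
  nh <- res$tag$NH
  nh <- if (is.null(nh)) rep(NA_integer_, sum(mapped)) else nh[mapped]

  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  start0 <- pos1 - 1L
  end0 <- start0 + width

  counts <- table(qname)
  default_hits <- as.integer(counts[qname])
  if (strict && any(!is.na(nh) & nh != default_hits)) {
    bad <- qname[which(!is.na(nh) & nh != default_hits)][1]
    cl_stop("InconsistentHitCount",
            "NH tag disagrees with record count for read %s", bad)
  }
  n_hits <- ifelse(is.na(nh), default_hits, nh)
  out <- data.frame(read_id = qname, ref = rname, start = start0, end = end0,
                    strand = strand, n_hits = as.integer(n_hits),
                    five_prime = ifelse(strand == "+", start0, end0 - 1L),
                    stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Write a minimal SAM file
#'
#' Used by the simulators to emit already-aligned degradome reads.
#'
#' @param records data.frame with `read_id`, `ref`, `pos` (0-based leftmost
#'   mapped base), `strand`, `seq` and `n_hits`.
#' @param ref_lengths named integer vector of reference lengths.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(records, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)), con)
  if (nrow(records) > 0L) {
    flag <- ifelse(records$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                       records$read_id, flag, records$ref,
                       records$pos + 1L, nchar(records$seq), records$seq,
                       as.integer(records$n_hits)), con)
  }
  invisible(path)
}
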