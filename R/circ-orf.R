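#' Rolling-circle sequence
#'
#' Concatenates the spliced circle sequence `copies` times (four by
#' default), the template scanned for circle-derived ORFs: four copies are
#' enough to expose every junction-spanning reading frame of circles in the
#' size range considered.
#'
#' @param circ_seq spliced circle sequence.
#' @param copies number of concatenated copies.
#' @return character scalar of length `copies * nchar(circ_seq)`.
#' @export
rolling_circle_seq <- function(circ_seq, copies = 4L) {
  if (nchar(circ_seq) < 1L) cl_stop("EmptySequence", "empty circle sequence")
  strrep(circ_seq, copies)
}

#' Predict ORFs from a circular sequence
#'
#' Scans the 4x concatenated circle (sense strand, all ATG starts with
#' start positions in the first copy) for ATG..stop ORFs and keeps those
#' longer than `min_aa` amino acids (strictly). An ORF whose coding span
#' crosses a multiple of the circle length spans the back-splice junction. A
#' reading frame with no stop anywhere in the periodic sequence is reported
#' once as a rolling ORF with its peptide truncated at four copies.
#'
#' @param circ_seq spliced circle sequence (>= 3 nt).
#' @param min_aa ORFs must exceed this length in amino acids.
#' @param id source id carried into `orf_id`.
#' @return data.frame with `orf_id`, `source`, `kind` ("cORF"), `frame`,
#'   `start` (0-based on the circle), `aa_length`, `peptide`,
#'   `spans_junction`, `rolling`.
#' @export
find_corfs <- function(circ_seq, min_aa = 10L, id = "circ") {
  L <- nchar(circ_seq)
  if (L < 3L) cl_stop("CircleTooShort", "circle of %d nt", L)
  seq4 <- rolling_circle_seq(circ_seq, 4L)
  total <- 4L * L
  starts <- gregexpr("ATG", substr(seq4, 1L, L + 2L), fixed = TRUE)[[1]]
  starts <- as.integer(starts[starts > 0 & starts <= L]) - 1L  # 0-based, in copy 1
  rows <- list()
  for (p in starts) {
    n_codons <- (total - p) %/% 3L
    codons <- substring(seq4, p + 1L + 3L * (seq_len(n_codons) - 1L),
                        p + 3L * seq_len(n_codons))
    stop_at <- which(codons %in% CODON_STOP)
    if (length(stop_at) > 0L) {
      aa_len <- stop_at[1L] - 1L
      rolling <- FALSE
    } else {
      aa_len <- n_codons
      rolling <- TRUE
    }
    if (aa_len <= min_aa) next
    pep <- translate_dna(paste(codons[seq_len(aa_len)], collapse = ""))
    rows[[length(rows) + 1L]] <- data.frame(
      source = id, kind = "cORF", frame = p %% 3L, start = p,
      aa_length = aa_len, peptide = pep,
      spans_junction = (p + 3L * aa_len) > L, rolling = rolling,
      stringsAsFactors = FALSE)
  }
  orfs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), kind = character(0), frame = integer(0),
               start = integer(0), aa_length = integer(0),
               peptide = character(0), spans_junction = logical(0),
               rolling = logical(0), stringsAsFactors = FALSE)
  orfs <- orfs[!duplicated(paste(orfs$start %% L, orfs$peptide)), ,
               drop = FALSE]
  if (nrow(orfs)) {
    orfs <- cbind(orf_id = sprintf("%s_cORF%02d", id, seq_len(nrow(orfs))),
                  orfs, stringsAsFactors = FALSE)
  } else {
    orfs <- cbind(orf_id = character(0), orfs, stringsAsFactors = FALSE)
  }
  rownames(orfs) <- NULL
  orfs
}

#' Predict uORFs and dORFs on a linear transcript
#'
#' ATG..stop ORFs entirely within the 5' UTR are uORFs, entirely within the
#' 3' UTR dORFs; ORFs overlapping the CDS are excluded (their count is
#' returned as attribute `n_overlapping`). The annotated CDS itself is
#' emitted as the primary ORF (pORF).
#'
#' @param transcript_seq mature transcript sequence.
#' @param cds_start,cds_end CDS bounds in transcript coordinates (0-based
#'   half-open, including the stop codon).
#' @param min_aa uORFs/dORFs must exceed this length in amino acids.
#' @param id source id.
#' @return data.frame as in [find_corfs()] with `kind` in
#'   `{uORF, dORF, pORF}` (no `spans_junction`/`rolling` semantics; both
#'   `FALSE`).
#' @export
find_uorfs_dorfs <- function(transcript_seq, cds_start, cds_end,
                             min_aa = 10L, id = "tx") {
  L <- nchar(transcript_seq)
  if (cds_start < 0L || cds_end > L || cds_end <= cds_start) {
    cl_stop("InvalidCDS", "CDS [%d,%d) outside transcript of %d nt",
            cds_start, cds_end, L)
  }
  chars <- transcript_seq
  starts <- gregexpr("ATG", chars, fixed = TRUE)[[1]]
  starts <- as.integer(starts[starts > 0]) - 1L
  rows <- list()
  n_overlap <- 0L
  for (p in starts) {
    n_codons <- (L - p) %/% 3L
    if (n_codons < 1L) next
    codons <- substring(chars, p + 1L + 3L * (seq_len(n_codons) - 1L),
                        p + 3L * seq_len(n_codons))
    stop_at <- which(codons %in% CODON_STOP)
    if (length(stop_at) == 0L) next           # no stop: not a complete ORF
    aa_len <- stop_at[1L] - 1L
    if (aa_len <= min_aa) next
    orf_end <- p + 3L * (aa_len + 1L)         # including the stop codon
    kind <- if (orf_end <= cds_start) "uORF"
            else if (p >= cds_end) "dORF"
            else if (p == cds_start && orf_end == cds_end) NA_character_
            else {
              n_overlap <- n_overlap + 1L
              NA_character_
            }
    if (is.na(kind)) next
    pep <- translate_dna(paste(codons[seq_len(aa_len)], collapse = ""))
    rows[[length(rows) + 1L]] <- data.frame(
      source = id, kind = kind, frame = p %% 3L, start = p,
      aa_length = aa_len, peptide = pep, spans_junction = FALSE,
      rolling = FALSE, stringsAsFactors = FALSE)
  }
  # annotated CDS as the primary ORF
  cds_seq <- substr(chars, cds_start + 1L, cds_end)
  pep <- sub("\\*$", "", translate_dna(cds_seq))
  rows[[length(rows) + 1L]] <- data.frame(
    source = id, kind = "pORF", frame = cds_start %% 3L, start = cds_start,
    aa_length = nchar(pep), peptide = pep, spans_junction = FALSE,
    rolling = FALSE, stringsAsFactors = FALSE)
  orfs <- do.call(rbind, rows)
  orfs <- cbind(orf_id = sprintf("%s_%s%02d", id, orfs$kind,
                                 stats::ave(seq_len(nrow(orfs)), orfs$kind,
                                            FUN = seq_along)),
                orfs, stringsAsFactors = FALSE)
  rownames(orfs) <- NULL
  attr(orfs, "n_overlapping") <- n_overlap
  orfs
}

#' Unique-peptide support filtering
#'
#' Peptides matching more (or fewer) than exactly one ORF are dropped; an
#' ORF is supported when at least one surviving peptide maps to it. Matching
#' is exact substring search of the peptide in each ORF peptide.
#'
#' @param peptides character vector of observed peptide sequences.
#' @param orf_peptides named character vector: ORF id -> ORF peptide.
#' @return list with `supported_orfs` (character), `dropped_peptides`
#'   (character) and `matches`, a data.frame of surviving peptide-ORF pairs.
#' @export
unique_peptide_filter <- function(peptides, orf_peptides) {
  stopifnot(all(nzchar(peptides)))
  hits <- lapply(peptides, function(p) {
    names(orf_peptides)[vapply(orf_peptides, function(o)
      grepl(p, o, fixed = TRUE), logical(1))]
  })
  n_hit <- lengths(hits)
  keep <- n_hit == 1L
  matches <- data.frame(peptide = peptides[keep],
                        orf_id = unlist(hits[keep], use.names = FALSE),
                        stringsAsFactors = FALSE)
  list(supported_orfs = unique(matches$orf_id),
       dropped_peptides = peptides[!keep],
       matches = matches)
}
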