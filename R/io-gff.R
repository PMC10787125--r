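#' Transcript model constructor
#'
#' Internal coordinates are 0-based half-open on the forward genomic strand;
#' exon order is genomic (by start). `cds` is in transcript coordinates
#' (0-based half-open along the spliced, strand-oriented transcript).
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with integer `start`, `end` (0-based half-open).
#' @param cds optional length-2 integer vector, CDS start/end in transcript
#'   coordinates.
#' @param strict if `TRUE`, require CDS length divisible by 3.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons,
                             cds = NULL, strict = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  check_interval(exons$start, exons$end, "exon")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    cl_stop("CoordinateError", "overlapping exons in %s", transcript_id)
  }
  tx_len <- sum(exons$end - exons$start)
  if (!is.null(cds)) {
    stopifnot(length(cds) == 2L)
    if (cds[1] < 0 || cds[2] > tx_len || cds[2] <= cds[1]) {
      cl_stop("CoordinateError", "CDS outside transcript %s", transcript_id)
    }
    if (strict && (cds[2] - cds[1]) %% 3L != 0L) {
      cl_stop("CoordinateError",
              "CDS length of %s not divisible by 3", transcript_id)
    }
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand,
                 start = exons$start[1L], end = exons$end[nrow(exons)],
                 exons = exons, cds = cds, length = tx_len),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d(%s) %d exon(s), %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), x$length))
  invisible(x)
}

#' Read gene models from GFF3 or GTF
#'
#' 1-based inclusive file coordinates are converted to the internal 0-based
#' half-open convention at this boundary. CDS features are mapped into
#' transcript coordinates.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @param strict require CDS lengths divisible by 3.
#' @return named list of [transcript_model] objects (by transcript id).
#' @export
read_gene_models <- function(path, strict = TRUE) {
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L          # to 0-based half-open
  df$end0 <- df$end
  type <- as.character(df$type)

  if (fmt == "gtf") {
    df$tx <- df$transcript_id
    df$gene <- df$gene_id
  } else {
    parent <- vapply(df$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    df$tx <- ifelse(type %in% c("exon", "CDS"), parent, df$ID)
    is_tx <- type %in% c("mRNA", "transcript")
    gene_of_tx <- setNames(parent[is_tx], df$ID[is_tx])
    df$gene <- NA_character_
    df$gene[type %in% c("exon", "CDS")] <-
      gene_of_tx[df$tx[type %in% c("exon", "CDS")]]
  }

  ex <- df[type == "exon", , drop = FALSE]
  if (any(is.na(ex$tx))) cl_stop("OrphanExon", "exon without a parent transcript")
  cds <- df[type == "CDS", , drop = FALSE]

  out <- list()
  for (tx_id in unique(ex$tx)) {
    e <- ex[ex$tx == tx_id, , drop = FALSE]
    gene_id <- e$gene[1L]
    if (is.na(gene_id)) gene_id <- tx_id
    strand <- as.character(e$strand[1L])
    exons <- data.frame(start = e$start0, end = e$end0)
    exons <- exons[order(exons$start), , drop = FALSE]
    cds_tx <- NULL
    cc <- cds[!is.na(cds$tx) & cds$tx == tx_id, , drop = FALSE]
    if (nrow(cc) > 0L) {
      gmin <- min(cc$start0); gmax <- max(cc$end0)
      m <- transcript_model(gene_id, tx_id, as.character(e$seqnames[1L]),
                            strand, exons, strict = FALSE)
      # genomic CDS bounds -> transcript coordinates, strand aware
      t1 <- genomic_to_transcript(m, gmin)
      t2 <- genomic_to_transcript(m, gmax - 1L)
      cds_tx <- c(min(t1, t2), max(t1, t2) + 1L)
    }
    out[[tx_id]] <- transcript_model(gene_id, tx_id,
                                     as.character(e$seqnames[1L]), strand,
                                     exons, cds = cds_tx, strict = strict)
  }
  out
}

#' Map a genomic position into transcript coordinates
#'
#' @param model a [transcript_model].
#' @param gpos 0-based genomic position(s) lying within an exon.
#' @return 0-based transcript coordinate(s) along the spliced transcript in
#'   its transcription direction.
#' @export
genomic_to_transcript <- function(model, gpos) {
  ex <- model$exons
  widths <- ex$end - ex$start
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  vapply(gpos, function(g) {
    i <- which(g >= ex$start & g < ex$end)
    if (length(i) != 1L) {
      cl_stop("CoordinateError", "position %d not exonic in %s",
              g, model$transcript_id)
    }
    plus <- offsets[i] + (g - ex$start[i])
    if (model$strand == "+") plus else model$length - 1L - plus
  }, numeric(1))
}

#' Map a transcript coordinate back to a genomic position
#'
#' Inverse of [genomic_to_transcript()].
#'
#' @param model a [transcript_model].
#' @param tpos 0-based transcript coordinate(s).
#' @return 0-based genomic position(s).
#' @export
transcript_to_genomic <- function(model, tpos) {
  ex <- model$exons
  widths <- ex$end - ex$start
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  vapply(tpos, function(t) {
    if (t < 0 || t >= model$length) {
      cl_stop("CoordinateError", "transcript position %d out of range", t)
    }
    plus <- if (model$strand == "+") t else model$length - 1L - t
    i <- findInterval(plus, offsets)
    ex$start[i] + (plus - offsets[i])
  }, numeric(1))
}

#' Spliced transcript sequence from a genome
#'
#' Exon sequences are concatenated in genomic order and reverse complemented
#' for minus-strand models, yielding the mature (5' to 3') sequence.
#'
#' @param model a [transcript_model] or anything with `chrom`, `strand` and an
#'   `exons` data.frame.
#' @param genome named character vector of chromosome sequences.
#' @return character scalar.
#' @export
spliced_seq <- function(model, genome) {
  chrom <- genome[[model$chrom]]
  if (is.null(chrom)) cl_stop("SequenceUnavailable", "no sequence for %s",
                              model$chrom)
  parts <- substring(chrom, model$exons$start + 1L, model$exons$end)
  s <- paste(parts, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}
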