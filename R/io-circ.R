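#' circRNA record constructor
#'
#' A back-spliced transcript: `start`/`end` are the back-splice acceptor and
#' donor genomic bounds (0-based half-open), `exons` is the exon chain in
#' genomic coordinates, and `junction_reads` counts reads spanning the
#' back-splice junction (per sample if named).
#'
#' @param id circRNA identifier.
#' @param chrom,strand genomic location.
#' @param start,end interval bounds (0-based half-open).
#' @param exons data.frame(start, end); defaults to the full interval.
#' @param junction_reads numeric, back-splice junction read count(s).
#' @param host_gene optional host gene id.
#' @param circ_type optional: "ecircRNA", "ciRNA" or "intergenic".
#' @return object of class `circ_rna`.
#' @export
circ_rna <- function(id, chrom, start, end, strand,
                     exons = data.frame(start = start, end = end),
                     junction_reads = 0, host_gene = NA_character_,
                     circ_type = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  check_interval(start, end, "circRNA")
  if (!strand %in% c("+", "-")) cl_stop("StrandMissing", "strand must be + or -")
  exons <- exons[order(exons$start), , drop = FALSE]
  check_interval(exons$start, exons$end, "circRNA exon")
  if (min(exons$start) < start || max(exons$end) > end) {
    cl_stop("BlockSumMismatch", "exon chain of %s exceeds its interval", id)
  }
  structure(list(id = id, chrom = chrom, start = start, end = end,
                 strand = strand, exons = exons,
                 junction_reads = junction_reads, host_gene = host_gene,
                 circ_type = circ_type),
            class = "circ_rna")
}

#' @export
print.circ_rna <- function(x, ...) {
  cat(sprintf("<circ_rna> %s %s:%d-%d(%s) %d exon(s) jr=%s type=%s\n",
              x$id, x$chrom, x$start, x$end, x$strand, nrow(x$exons),
              paste(x$junction_reads, collapse = ","), x$circ_type))
  invisible(x)
}

#' Read a circRNA table (BED6/BED12 dialect)
#'
#' The dialect follows common circRNA-caller output: column 5 (score)
#' carries the back-splice junction read count; 12-column rows define the
#' exon chain through blockSizes/blockStarts; 6-column rows get a
#' single-exon chain spanning the whole interval.
#'
#' @param path BED file.
#' @return named list of [circ_rna] objects.
#' @export
read_circ_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6L) cl_stop("MalformedBed", "need >= 6 BED columns")
  out <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    chrom <- as.character(r[[1]]); start <- as.integer(r[[2]])
    end <- as.integer(r[[3]]); id <- as.character(r[[4]])
    score <- as.numeric(r[[5]]); strand <- as.character(r[[6]])
    if (!strand %in% c("+", "-")) cl_stop("StrandMissing",
                                          "row %d: strand missing", i)
    has_blocks <- ncol(df) >= 12L && !is.na(r[[10]]) &&
      !is.na(r[[11]]) && nzchar(r[[11]])
    if (has_blocks) {
      nb <- as.integer(r[[10]])
      sizes <- as.integer(strsplit(as.character(r[[11]]), ",")[[1]])[seq_len(nb)]
      bstarts <- as.integer(strsplit(as.character(r[[12]]), ",")[[1]])[seq_len(nb)]
      if (any(bstarts + sizes > end - start)) {
        cl_stop("BlockSumMismatch", "row %d: blocks exceed interval", i)
      }
      exons <- data.frame(start = start + bstarts, end = start + bstarts + sizes)
    } else {
      exons <- data.frame(start = start, end = end)
    }
    out[[id]] <- circ_rna(id, chrom, start, end, strand, exons,
                          junction_reads = score)
  }
  out
}

#' Write circRNAs as BED12
#'
#' Inverse of [read_circ_table()]; `read(write(x))` reproduces the records.
#'
#' @param circs list of [circ_rna].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_circ_table <- function(circs, path) {
  lines <- vapply(circs, function(cr) {
    sizes <- cr$exons$end - cr$exons$start
    bstarts <- cr$exons$start - cr$start
    paste(cr$chrom, cr$start, cr$end, cr$id,
          cr$junction_reads[[1]], cr$strand, cr$start, cr$end, "0",
          nrow(cr$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(bstarts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Spliced circle sequence
#'
#' Concatenates the circRNA exon chain and orients it 5' to 3'.
#'
#' @param circ a [circ_rna].
#' @param genome named character vector of chromosome sequences.
#' @return character scalar.
#' @export
circ_spliced_seq <- function(circ, genome) spliced_seq(circ, genome)
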