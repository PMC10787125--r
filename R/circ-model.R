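#' Classify a circRNA as exonic, intronic or intergenic
#'
#' An ecircRNA overlaps at least one annotated exon of a same-strand
#' transcript; a ciRNA lies entirely within a single annotated intron (and
#' overlaps no exon); anything else is intergenic. Exon overlap takes
#' precedence over intron containment.
#'
#' @param circ a [circ_rna].
#' @param models list of [transcript_model]s.
#' @return one of "ecircRNA", "ciRNA", "intergenic".
#' @export
classify_circ_type <- function(circ, models) {
  in_intron <- FALSE
  for (m in models) {
    if (m$chrom != circ$chrom || m$strand != circ$strand) next
    ex <- m$exons
    if (any(ex$start < circ$end & ex$end > circ$start)) return("ecircRNA")
    if (nrow(ex) > 1L) {
      istart <- ex$end[-nrow(ex)]
      iend <- ex$start[-1L]
      if (any(circ$start >= istart & circ$end <= iend)) in_intron <- TRUE
    }
  }
  if (in_intron) "ciRNA" else "intergenic"
}

# Back-splice boundary convention: in transcript orientation the circle's 3'
# (donor) boundary is the genomic end on "+" and the genomic start on "-";
# the acceptor is the opposite bound.
bs_boundaries <- function(circ) {
  if (circ$strand == "+") c(donor = circ$end, acceptor = circ$start)
  else c(donor = circ$start, acceptor = circ$end)
}

#' Classify alternative back-splicing between circRNAs of one gene
#'
#' For each unordered pair of same-gene, same-strand circRNAs: A5BS when the
#' two share the back-splice donor boundary but differ at the acceptor; A3BS
#' when they share the acceptor but differ at the donor; MIC (mutually
#' inclusive circRNAs) when their intervals partially overlap (neither
#' contains the other) and each contains at least one exon absent from the
#' other. A5BS/A3BS take precedence over MIC; a pair gets at most one label.
#'
#' @param circs list of [circ_rna] sharing a host gene.
#' @return data.frame with `circ_a`, `circ_b`, `label`.
#' @export
classify_alt_backsplicing <- function(circs) {
  if (length(circs) < 2L) {
    return(data.frame(circ_a = character(0), circ_b = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  strands <- vapply(circs, `[[`, character(1), "strand")
  if (length(unique(strands)) > 1L) {
    cl_stop("StrandMismatch", "circRNAs of one gene group must share strand")
  }
  rows <- list()
  idx <- utils::combn(length(circs), 2L)
  for (p in seq_len(ncol(idx))) {
    a <- circs[[idx[1L, p]]]; b <- circs[[idx[2L, p]]]
    ba <- bs_boundaries(a); bb <- bs_boundaries(b)
    label <- NA_character_
    if (ba["donor"] == bb["donor"] && ba["acceptor"] != bb["acceptor"]) {
      label <- "A5BS"
    } else if (ba["acceptor"] == bb["acceptor"] && ba["donor"] != bb["donor"]) {
      label <- "A3BS"
    } else if (ba["donor"] != bb["donor"] && ba["acceptor"] != bb["acceptor"]) {
      partial <- a$start < b$end && b$start < a$end &&
        !(a$start <= b$start && a$end >= b$end) &&
        !(b$start <= a$start && b$end >= a$end)
      if (partial) {
        ea <- paste(a$exons$start, a$exons$end)
        eb <- paste(b$exons$start, b$exons$end)
        if (length(setdiff(ea, eb)) > 0L && length(setdiff(eb, ea)) > 0L) {
          label <- "MIC"
        }
      }
    }
    if (!is.na(label)) {
      rows[[length(rows) + 1L]] <- data.frame(circ_a = a$id, circ_b = b$id,
                                              label = label,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(circ_a = character(0), circ_b = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify internal alternative splicing between circRNA isoforms
#'
#' Compares exon chains of circRNA isoforms sharing both back-splice sites.
#' Per pair: an exon wholly present in one chain and absent (unoverlapped)
#' in the other is exon skipping (ExonS); a chain continuous across an
#' intron spliced in the other is intron retention (IntronR); a shared exon
#' differing only at its 3' splice boundary is A3SS, at its 5' boundary
#' A5SS. Labels accumulate per pair.
#'
#' @param isoforms list of [circ_rna] with identical outer boundaries.
#' @return data.frame with `circ_a`, `circ_b`, `label` (one row per label).
#' @export
classify_internal_as <- function(isoforms) {
  if (length(isoforms) < 2L) {
    return(data.frame(circ_a = character(0), circ_b = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  outer <- vapply(isoforms, function(x) paste(x$start, x$end), character(1))
  if (length(unique(outer)) > 1L) {
    cl_stop("BoundaryMismatch", "isoforms must share both back-splice sites")
  }
  strand <- isoforms[[1L]]$strand
  rows <- list()
  idx <- utils::combn(length(isoforms), 2L)
  for (p in seq_len(ncol(idx))) {
    a <- isoforms[[idx[1L, p]]]; b <- isoforms[[idx[2L, p]]]
    labels <- union(chain_as_labels(a$exons, b$exons, strand),
                    chain_as_labels(b$exons, a$exons, strand))
    for (lb in labels) {
      rows[[length(rows) + 1L]] <- data.frame(circ_a = a$id, circ_b = b$id,
                                              label = lb,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(circ_a = character(0), circ_b = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# One-directional chain comparison feeding classify_internal_as().
chain_as_labels <- function(ea, eb, strand) {
  labels <- character(0)
  for (i in seq_len(nrow(ea))) {
    s <- ea$start[i]; e <- ea$end[i]
    ov <- which(eb$start < e & eb$end > s)
    if (length(ov) == 0L) {
      labels <- c(labels, "ExonS")
    } else if (length(ov) >= 2L) {
      # one exon of A spans several exons of B -> A retains B's intron(s)
      labels <- c(labels, "IntronR")
    } else {
      f <- ov[1L]
      # a 1:1 exon correspondence is required for a splice-site shift call;
      # if B's exon spans several exons of A the event is intron retention
      # (reported when scanning from B's side)
      back <- sum(ea$start < eb$end[f] & ea$end > eb$start[f])
      if (back >= 2L) next
      same_start <- eb$start[f] == s
      same_end <- eb$end[f] == e
      if (same_start && !same_end) {
        # differ at genomic end: donor (5') side on "+", acceptor (3') on "-"
        labels <- c(labels, if (strand == "+") "A5SS" else "A3SS")
      } else if (!same_start && same_end) {
        labels <- c(labels, if (strand == "+") "A3SS" else "A5SS")
      } else if (!same_start && !same_end) {
        labels <- c(labels, if (strand == "+") "A3SS" else "A5SS",
                    if (strand == "+") "A5SS" else "A3SS")
      }
    }
  }
  unique(labels)
}

#' RPM normalization of junction counts
#'
#' value = count / (mapped_total / 1e6): reads spanning the back-splice
#' junction per million mapped reads.
#'
#' @param counts numeric matrix or data.frame (rows = circRNAs, columns =
#'   samples).
#' @param mapped_totals numeric vector of per-sample mapped read totals.
#' @return matrix of RPM values with a `normalization` attribute.
#' @export
rpm_normalize <- function(counts, mapped_totals) {
  counts <- as.matrix(counts)
  if (length(mapped_totals) != ncol(counts)) {
    stop("one mapped total per sample required", call. = FALSE)
  }
  if (any(mapped_totals <= 0)) cl_stop("ZeroLibrary", "mapped total must be > 0")
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  out <- sweep(counts, 2L, mapped_totals / 1e6, "/")
  attr(out, "normalization") <- "RPM"
  out
}

#' Fold change between two RPM values
#'
#' Ratio of treatment over control. A pseudocount of 0.5 RPM is added to
#' both sides only when either side is zero, so that finite ratios exist for
#' condition-specific circRNAs while exact ratios are preserved otherwise;
#' either way fc(a,b) * fc(b,a) = 1.
#'
#' @param rpm_trt,rpm_ctl non-negative RPM values.
#' @param pseudocount value added to both sides when either is zero.
#' @return numeric fold change.
#' @export
fold_change <- function(rpm_trt, rpm_ctl, pseudocount = 0.5) {
  pc <- ifelse(rpm_trt == 0 | rpm_ctl == 0, pseudocount, 0)
  (rpm_trt + pc) / (rpm_ctl + pc)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values.
#' @return vector of BH-adjusted values (same order as input).
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Differential circRNA expression between two conditions
#'
#' Replicates are pooled by summation per condition. The significance test
#' is an exact two-proportion binomial comparison: for junction counts
#' (k1, k2) under library totals (N1, N2), p is the two-sided exact binomial
#' test of k1 successes in k1 + k2 trials with success probability
#' N1 / (N1 + N2). Fold change is computed on RPM (treatment over control)
#' via [fold_change()], FDR by Benjamini-Hochberg, and a circRNA is called
#' up/down only under the triple cutoff fold change >= `fc_cut` (or <=
#' 1/`fc_cut`), p < `p_cut` and FDR <= `fdr_cut`.
#'
#' @param counts_trt,counts_ctl named numeric vectors of junction counts
#'   (same ids).
#' @param total_trt,total_ctl mapped read totals for the two conditions.
#' @param fc_cut,p_cut,fdr_cut cutoffs (defaults 2, 0.01, 0.01).
#' @return data.frame with `id`, `rpm_trt`, `rpm_ctl`, `fold_change`,
#'   `p_value`, `fdr`, `direction`.
#' @export
differential_circrnas <- function(counts_trt, counts_ctl,
                                  total_trt, total_ctl,
                                  fc_cut = 2, p_cut = 0.01, fdr_cut = 0.01) {
  stopifnot(identical(names(counts_trt), names(counts_ctl)))
  if (total_trt <= 0 || total_ctl <= 0) cl_stop("ZeroLibrary",
                                                "library totals must be > 0")
  rpm_t <- as.numeric(rpm_normalize(cbind(counts_trt), total_trt))
  rpm_c <- as.numeric(rpm_normalize(cbind(counts_ctl), total_ctl))
  fc <- fold_change(rpm_t, rpm_c)
  p0 <- total_trt / (total_trt + total_ctl)
  pv <- vapply(seq_along(counts_trt), function(i) {
    k1 <- round_half_up(counts_trt[i]); k2 <- round_half_up(counts_ctl[i])
    if (k1 + k2 == 0) return(1)
    stats::binom.test(k1, k1 + k2, p = p0)$p.value
  }, numeric(1))
  fdr <- bh_adjust(pv)
  sig <- pv < p_cut & fdr <= fdr_cut
  direction <- ifelse(sig & fc >= fc_cut, "up",
                      ifelse(sig & fc <= 1 / fc_cut, "down", "ns"))
  data.frame(id = names(counts_trt), rpm_trt = rpm_t, rpm_ctl = rpm_c,
             fold_change = fc, p_value = pv, fdr = fdr,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson correlation of two expression profiles
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param high_cut absolute-correlation threshold for the high flag.
#' @return list with `r` and logical `high` (`|r| >= high_cut`).
#' @export
pearson_profile <- function(x, y, high_cut = 0.5) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    cl_stop("ConstantVector", "correlation undefined for a constant profile")
  }
  r <- stats::cor(x, y)
  list(r = r, high = abs(r) >= high_cut)
}
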