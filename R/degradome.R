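#' Build weighted 5'-end pileups
#'
#' Each alignment contributes `1/n_hits` at its 5'-end position so that every
#' sequenced read carries total weight 1 regardless of how many loci it was
#' reported at. Strands are kept separate.
#'
#' @param reads data.frame as returned by [read_alignments_5p()].
#' @param ref_lengths named integer vector giving each reference length.
#' @return named list of pileups keyed `"<ref>:<strand>"`; each is a list
#'   with `ref`, `strand`, `length` and a numeric `weights` vector (one cell
#'   per reference position).
#' @export
build_5p_pileup <- function(reads, ref_lengths) {
  if (any(reads$five_prime < 0) ||
      any(reads$five_prime >= ref_lengths[reads$ref])) {
    cl_stop("PositionOutOfRange", "5' end outside its reference")
  }
  key <- paste(reads$ref, reads$strand, sep = ":")
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    ref <- reads$ref[sel][1L]
    L <- as.integer(ref_lengths[[ref]])
    w <- numeric(L)
    tab <- tapply(1 / reads$n_hits[sel], reads$five_prime[sel], sum)
    w[as.integer(names(tab)) + 1L] <- as.numeric(tab)
    out[[k]] <- list(ref = ref, strand = reads$strand[sel][1L],
                     length = L, weights = w)
  }
  out
}

#' Upper-tail binomial probability
#'
#' P(X >= k) for X ~ Binomial(N, p0), used as the significance measure for a
#' candidate cleavage position carrying k of N reads under a uniform-decay
#' null.
#'
#' @param k observed count (0 <= k <= N).
#' @param N number of trials (>= 1).
#' @param p0 null per-trial probability in (0, 1).
#' @return p-value in `[0, 1]`.
#' @export
binomial_peak_pvalue <- function(k, N, p0) {
  if (N < 1L || k < 0L || k > N || p0 <= 0 || p0 >= 1) {
    cl_stop("InvalidParameters", "need 0 <= k <= N, N >= 1, p0 in (0,1)")
  }
  if (k == 0L) return(1)
  stats::pbinom(k - 1L, N, p0, lower.tail = FALSE)
}

#' Call degradome cleavage peaks
#'
#' A position is a peak when it carries at least `min_fraction` of the
#' 5'-end weight in its centred window of `2*half_window + 1` nt (truncated
#' at reference ends, with the denominator restricted to existing positions)
#' and its binomial upper-tail p-value is at most `alpha`. Weights are kept
#' fractional for the window rule; k and N are rounded half-up only at the
#' test boundary. Under `null_mode = "transcript"` (default) the null is
#' uniform decay over the reference: p0 = 1/length, N = rounded total
#' reference weight. Under `"window"`, p0 = 1/(2*half_window+1) and N is the
#' rounded window total.
#'
#' @param pileup one element of [build_5p_pileup()] output.
#' @param half_window window half width in nt.
#' @param min_fraction minimum within-window weight fraction.
#' @param alpha p-value cutoff.
#' @param null_mode "transcript" or "window".
#' @param fdr if `TRUE`, apply Benjamini-Hochberg across candidate positions
#'   and filter on the adjusted values instead of raw p.
#' @return data.frame with `ref`, `strand`, `pos` (0-based), `weight`,
#'   `window_total`, `fraction`, `p_value`.
#' @export
call_degradome_peaks <- function(pileup, half_window = 10L,
                                 min_fraction = 0.5, alpha = 0.05,
                                 null_mode = c("transcript", "window"),
                                 fdr = FALSE) {
  null_mode <- match.arg(null_mode)
  w <- pileup$weights
  L <- pileup$length
  if (L == 0L || all(w == 0)) cl_stop("EmptyPileup", "pileup has no weight")
  total <- sum(w)
  # windowed sums with truncation at the ends
  cs <- cumsum(c(0, w))
  idx <- seq_len(L)
  lo <- pmax(idx - half_window, 1L)
  hi <- pmin(idx + half_window, L)
  win <- cs[hi + 1L] - cs[lo]
  cand <- which(w > 0 & w / win >= min_fraction)
  if (length(cand) == 0L) return(empty_peaks(pileup))
  k <- round_half_up(w[cand])
  if (null_mode == "transcript") {
    N <- rep(round_half_up(total), length(cand))
    p0 <- 1 / L
  } else {
    N <- round_half_up(win[cand])
    p0 <- 1 / (2 * half_window + 1)
  }
  pv <- vapply(seq_along(cand), function(i) {
    if (k[i] < 1L || N[i] < 1L) return(1)
    binomial_peak_pvalue(min(k[i], N[i]), N[i], p0)
  }, numeric(1))
  crit <- if (fdr) bh_adjust(pv) else pv
  keep <- which(crit <= alpha & k >= 1L)
  if (length(keep) == 0L) return(empty_peaks(pileup))
  data.frame(ref = pileup$ref, strand = pileup$strand,
             pos = cand[keep] - 1L, weight = w[cand][keep],
             window_total = win[cand][keep],
             fraction = (w[cand] / win[cand])[keep],
             p_value = pv[keep], stringsAsFactors = FALSE)
}

empty_peaks <- function(pileup) {
  data.frame(ref = character(0), strand = character(0), pos = integer(0),
              weight = numeric(0), window_total = numeric(0),
              fraction = numeric(0), p_value = numeric(0),
              stringsAsFactors = FALSE)
}

#' Locate a cleavage peak relative to a circRNA body
#'
#' Upstream/downstream are in transcription direction: on the minus strand,
#' genomic positions beyond the circle's genomic end are upstream.
#'
#' @param pos 0-based genomic peak position.
#' @param circ a [circ_rna] on the same chromosome.
#' @param chrom chromosome of the peak (checked against the circle).
#' @return one of "upstream", "within", "downstream".
#' @export
locate_peak_vs_circ <- function(pos, circ, chrom = circ$chrom) {
  if (!identical(chrom, circ$chrom)) {
    cl_stop("ChromMismatch", "peak on %s, circRNA on %s", chrom, circ$chrom)
  }
  if (pos >= circ$start && pos < circ$end) return("within")
  before <- pos < circ$start
  if (circ$strand == "+") {
    if (before) "upstream" else "downstream"
  } else {
    if (before) "downstream" else "upstream"
  }
}
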