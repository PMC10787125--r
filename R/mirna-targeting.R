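#' Extract the target context around a cleavage site
#'
#' Takes `flank` nt on each side of the site (25 by default, giving a 51-nt
#' window). Linear transcripts truncate at their ends; circular transcripts
#' wrap across the back-splice junction (periodic sequence) and never
#' truncate.
#'
#' @param transcript_seq transcript sequence (5' to 3').
#' @param site 0-based cleavage position on the transcript.
#' @param flank nt of context on each side.
#' @param circular is the transcript a circle?
#' @param transcript_id carried through to the result.
#' @return list with `transcript_id`, `center` (the site), `seq`,
#'   `start` (transcript coordinate of window position 0; may exceed the
#'   circle length conceptually — use [window_to_transcript()]),
#'   `center_index`, `left_truncated`, `right_truncated`, `circular`,
#'   `transcript_length`.
#' @export
extract_cleavage_context <- function(transcript_seq, site, flank = 25L,
                                     circular = FALSE,
                                     transcript_id = NA_character_) {
  L <- nchar(transcript_seq)
  if (site < 0L || site >= L) {
    cl_stop("SiteOutOfRange", "site %d outside transcript of length %d",
            site, L)
  }
  if (circular) {
    start <- site - flank
    seq <- periodic_substr(transcript_seq, start %% L, 2L * flank + 1L)
    list(transcript_id = transcript_id, center = site, seq = seq,
         start = start, center_index = flank,
         left_truncated = FALSE, right_truncated = FALSE,
         circular = TRUE, transcript_length = L)
  } else {
    start <- max(0L, site - flank)
    end <- min(L, site + flank + 1L)
    list(transcript_id = transcript_id, center = site,
         seq = substr(transcript_seq, start + 1L, end),
         start = start, center_index = site - start,
         left_truncated = site - flank < 0L,
         right_truncated = site + flank + 1L > L,
         circular = FALSE, transcript_length = L)
  }
}

#' Transcript coordinate of a window position
#'
#' @param window result of [extract_cleavage_context()].
#' @param idx 0-based index within the window.
#' @return 0-based transcript coordinate (wrapped modulo the circle length
#'   for circular windows).
#' @export
window_to_transcript <- function(window, idx) {
  pos <- window$start + idx
  if (window$circular) pos %% window$transcript_length else pos
}

# Pairing energies of the simplified duplex model (negative = stabilizing).
duplex_pair_energy <- function(a, b,
                               e_gc = -3, e_at = -2, e_gt = -1) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(e_gc)
  if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(e_at)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(e_gt)
  NA_real_
}

#' Duplex energy parameters
#'
#' @param e_gc,e_at,e_gt pair energies (G:C, A:T, G:T wobble).
#' @param bulge penalty per unpaired base inside the duplex.
#' @param mismatch penalty per opposed non-pairing base pair.
#' @return named list of parameters.
#' @export
duplex_params <- function(e_gc = -3, e_at = -2, e_gt = -1,
                          bulge = 2, mismatch = 1) {
  list(e_gc = e_gc, e_at = e_at, e_gt = e_gt,
       bulge = bulge, mismatch = mismatch)
}

#' Align a miRNA against a target window (simplified duplex MFE model)
#'
#' Antiparallel co-alignment: the miRNA 5'->3' pairs against the window read
#' 3'->5'. The model scores G:C = -3, A:T = -2, G:T = -1; each unpaired base
#' inside the duplex costs +2 (bulge/internal loop) and each opposed
#' non-pairing position +1 (mismatch); bases outside the first and last pair
#' are free ("ends open"). The reported energy E is the minimum over all
#' such duplexes (E = 0 when no pairing helps), and the MFE ratio is E
#' divided by the energy of the miRNA bound to its exact complement.
#'
#' This is a deliberately simplified nearest-pair model, not a
#' Turner-parameter thermodynamic engine: the downstream decision is a
#' ratio threshold, for which a monotone, exactly testable model suffices.
#'
#' @param mirna_seq miRNA sequence, 5' to 3' (T alphabet).
#' @param window result of [extract_cleavage_context()] or a plain character
#'   scalar.
#' @param params energies from [duplex_params()].
#' @return list of class `duplex_alignment`: `energy`, `perfect_energy`,
#'   `mfe_ratio` and `pairs`, a data.frame of (`mirna_pos` 1-based from the
#'   miRNA 5' end, `window_pos` 0-based in the window).
#' @export
duplex_align <- function(mirna_seq, window, params = duplex_params()) {
  wseq <- if (is.list(window)) window$seq else window
  n <- nchar(mirna_seq)
  m <- nchar(wseq)
  if (m < n * 0.5) cl_stop("WindowTooShort", "window (%d nt) too short", m)
  a <- strsplit(mirna_seq, "")[[1]]
  b <- rev(strsplit(wseq, "")[[1]])     # antiparallel: co-linear vs reversed

  # pair-energy lookup table over the 5-letter alphabet
  alpha <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
  M5 <- matrix(NA_real_, 5, 5)
  M5[3, 2] <- M5[2, 3] <- params$e_gc
  M5[1, 4] <- M5[4, 1] <- params$e_at
  M5[3, 4] <- M5[4, 3] <- params$e_gt
  ai <- alpha[a]; bi <- alpha[b]
  E <- matrix(M5[cbind(rep(ai, times = m), rep(bi, each = n))], n, m)

  P <- matrix(Inf, n, m)                # best duplex ending in pair (i,j)
  Q <- matrix(Inf, n, m)                # best prefix ending at (i,j), >=1 pair
  mm <- params$mismatch; bg <- params$bulge
  qprev <- rep(Inf, m)                  # Q[i-1, ]
  for (i in seq_len(n)) {
    ei <- E[i, ]
    pi_ <- rep(Inf, m)
    # pair column: open fresh (leading overhang free) or extend Q[i-1,j-1]
    prev <- c(Inf, qprev[-m])
    open <- pmin(0, prev)
    open[1L] <- 0
    pi_ <- ei + open
    pi_[is.na(pi_)] <- Inf
    # Q row: min(P, diag mismatch, up bulge) then running left-bulge pass
    qi <- pmin(pi_, prev + mm, qprev + bg)
    acc <- Inf
    for (j in seq_len(m)) {
      v <- min(qi[j], acc + bg)
      qi[j] <- v
      acc <- v
    }
    P[i, ] <- pi_
    Q[i, ] <- qi
    qprev <- qi
  }
  perfect <- sum(ifelse(a %in% c("G", "C"), params$e_gc,
                        ifelse(a %in% c("A", "T"), params$e_at, 0)))
  best <- min(P)
  if (best >= 0) {
    out <- list(energy = 0, perfect_energy = perfect, mfe_ratio = 0,
                pairs = data.frame(mirna_pos = integer(0),
                                   window_pos = integer(0)))
    class(out) <- "duplex_alignment"
    return(out)
  }
  # deterministic argmin: smallest i, then smallest j
  hit <- which(P == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
  pairs <- duplex_traceback(hit[1L], hit[2L], P, Q, E, params)
  out <- list(energy = best, perfect_energy = perfect,
              mfe_ratio = if (perfect < 0) best / perfect else 0,
              pairs = data.frame(mirna_pos = pairs[, 1L],
                                 window_pos = m - pairs[, 2L]))
  class(out) <- "duplex_alignment"
  out
}

# Recover the paired positions of the optimal duplex ending at pair (i, j).
duplex_traceback <- function(i, j, P, Q, E, params) {
  pairs <- matrix(integer(0), 0, 2)
  repeat {
    pairs <- rbind(c(i, j), pairs)
    if (i == 1L || j == 1L) break
    prevq <- Q[i - 1L, j - 1L]
    if (prevq >= 0 || abs(P[i, j] - E[i, j]) < 1e-9) break  # duplex starts here
    # descend into Q at (i-1, j-1)
    i <- i - 1L; j <- j - 1L
    repeat {
      v <- Q[i, j]
      if (is.finite(P[i, j]) && abs(v - P[i, j]) < 1e-9) break
      if (i > 1L && j > 1L && abs(v - (Q[i - 1L, j - 1L] + params$mismatch)) < 1e-9) {
        i <- i - 1L; j <- j - 1L
      } else if (i > 1L && abs(v - (Q[i - 1L, j] + params$bulge)) < 1e-9) {
        i <- i - 1L
      } else if (j > 1L && abs(v - (Q[i, j - 1L] + params$bulge)) < 1e-9) {
        j <- j - 1L
      } else {
        break
      }
    }
  }
  pairs
}

#' Predicted slice position of a duplex
#'
#' Plant miRNA-guided cleavage falls between target bases opposite miRNA
#' positions 10 and 11; the reported coordinate is the target base paired
#' with miRNA position 10 (1-based from the miRNA 5' end).
#'
#' @param duplex a `duplex_alignment`.
#' @param window the window the duplex was computed on.
#' @return 0-based transcript coordinate of the predicted slice.
#' @export
predicted_slice_position <- function(duplex, window) {
  hit <- duplex$pairs$window_pos[duplex$pairs$mirna_pos == 10L]
  if (length(hit) != 1L) {
    cl_stop("Position10Unpaired", "miRNA position 10 is not paired")
  }
  window_to_transcript(window, hit)
}

#' Call miRNA-mediated cleavage at degradome peaks
#'
#' For every peak x miRNA combination: extract the 51-nt context, align
#' under the duplex model, require MFE ratio >= `min_ratio` (or <=, with
#' `ratio_sense = "le"`) and predicted slice within `max_offset` nt of the
#' peak. All passing combinations are reported.
#'
#' @param peaks data.frame from [call_degradome_peaks()] with transcript
#'   references.
#' @param transcripts named character vector of transcript sequences.
#' @param mirnas named character vector of mature miRNA sequences.
#' @param is_circ named logical: is each transcript circular?
#' @param min_ratio MFE-ratio threshold.
#' @param max_offset maximum |predicted slice - peak| in nt.
#' @param ratio_sense `"ge"` keeps duplexes at least `min_ratio` as stable as
#'   the perfect duplex (conventional reading); `"le"` flips the comparison.
#' @param flank context flank, nt.
#' @param params duplex model parameters.
#' @return data.frame with `transcript`, `peak_pos`, `mirna`, `mfe_ratio`,
#'   `slice_pos`, `slice_offset`, `is_circ`.
#' @export
call_mirna_cleavage <- function(peaks, transcripts, mirnas,
                                is_circ = setNames(rep(FALSE,
                                  length(transcripts)), names(transcripts)),
                                min_ratio = 0.7, max_offset = 1L,
                                ratio_sense = c("ge", "le"),
                                flank = 25L, params = duplex_params()) {
  ratio_sense <- match.arg(ratio_sense)
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    tx <- peaks$ref[i]
    if (is.null(transcripts[[tx]])) next
    circ <- isTRUE(is_circ[[tx]])
    win <- extract_cleavage_context(transcripts[[tx]], peaks$pos[i],
                                    flank = flank, circular = circ,
                                    transcript_id = tx)
    for (mi in seq_along(mirnas)) {
      dx <- duplex_align(mirnas[[mi]], win, params = params)
      ok_ratio <- if (ratio_sense == "ge") dx$mfe_ratio >= min_ratio
                  else dx$mfe_ratio <= min_ratio
      if (!ok_ratio) next
      slice <- tryCatch(predicted_slice_position(dx, win),
                        Position10Unpaired = function(e) NULL)
      if (is.null(slice)) next
      d <- abs(slice - peaks$pos[i])
      if (circ) d <- min(d, win$transcript_length - d)
      if (d > max_offset) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = tx, peak_pos = peaks$pos[i], mirna = names(mirnas)[mi],
        mfe_ratio = dx$mfe_ratio, slice_pos = slice, slice_offset = d,
        is_circ = circ, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript = character(0), peak_pos = integer(0),
                      mirna = character(0), mfe_ratio = numeric(0),
                      slice_pos = integer(0), slice_offset = integer(0),
                      is_circ = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify a small-RNA read against known miRNAs
#'
#' A read identical to a known miRNA is conserved; otherwise it is a variant
#' when within edit distance 3 (mismatches plus gaps) of some known miRNA,
#' else unclassified. The best match is the minimum-distance miRNA, ties
#' broken by input order.
#'
#' @param read_seq read sequence (18-26 nt, T alphabet).
#' @param known named character vector of known mature miRNAs.
#' @param max_edits variant threshold.
#' @return list with `class` ("conserved", "variant" or "none"),
#'   `best_match` and `distance`.
#' @export
classify_mirna_read <- function(read_seq, known, max_edits = 3L) {
  n <- nchar(read_seq)
  if (n < 18L || n > 26L) {
    cl_stop("LengthOutOfRange", "read length %d outside 18-26", n)
  }
  d <- as.integer(adist(read_seq, known))
  best <- which.min(d)
  cls <- if (d[best] == 0L) "conserved"
         else if (d[best] <= max_edits) "variant"
         else "none"
  list(class = cls,
       best_match = if (cls == "none") NA_character_ else names(known)[best],
       distance = d[best])
}
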