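# Shared fixture builders and independent oracles used across test files.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small two-exon plus-strand transcript on a hand-made chromosome.
toy_models <- function() {
  list(
    txA = transcript_model("geneA", "txA", "chr1", "+",
                           data.frame(start = c(10L, 30L), end = c(20L, 40L))),
    txB = transcript_model("geneB", "txB", "chr1", "-",
                           data.frame(start = c(100L, 140L, 180L),
                                      end = c(120L, 160L, 200L)))
  )
}

# Write a minimal GFF3 for hand-specified exon/CDS rows.
write_toy_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

write_toy_sam <- function(records, ref_lengths,
                          path = tempfile(fileext = ".sam")) {
  write_sam(records, ref_lengths, path)
  path
}

# --- Independent oracles ----------------------------------------------------

# Exact binomial upper tail by direct summation of the mass function.
oracle_binom_tail <- function(k, N, p0) {
  if (k == 0) return(1)
  i <- k:N
  sum(choose(N, i) * p0^i * (1 - p0)^(N - i))
}

# Brute-force per-position peak evaluation (re-states the definition,
# independently of the vectorized caller).
oracle_peaks <- function(pileup, half_window = 10L, min_fraction = 0.5,
                         alpha = 0.05, null_mode = "transcript") {
  w <- pileup$weights
  L <- pileup$length
  total <- sum(w)
  out <- list()
  for (i in seq_len(L)) {
    if (w[i] <= 0) next
    lo <- max(1L, i - half_window); hi <- min(L, i + half_window)
    W <- sum(w[lo:hi])
    if (w[i] / W < min_fraction) next
    k <- floor(w[i] + 0.5)
    if (k < 1) next
    if (null_mode == "transcript") {
      N <- floor(total + 0.5); p0 <- 1 / L
    } else {
      N <- floor(W + 0.5); p0 <- 1 / (2 * half_window + 1)
    }
    if (N < 1) next
    p <- oracle_binom_tail(min(k, N), N, p0)
    if (p <= alpha) {
      out[[length(out) + 1L]] <- data.frame(pos = i - 1L, weight = w[i],
                                            p_value = p)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pos = integer(0), weight = numeric(0),
                      p_value = numeric(0)))
  }
  do.call(rbind, out)
}

# Quartic-time duplex DP over explicit "last pair" predecessors, with the
# interior cost between consecutive pairs computed combinatorially:
# min(di, dj) mismatch columns at +1 plus |di - dj| single-base bulges at +2.
# Structurally independent of the package's linear three-state recurrence.
oracle_duplex_energy <- function(mirna, window, params = duplex_params()) {
  a <- strsplit(mirna, "")[[1]]
  b <- rev(strsplit(window, "")[[1]])
  n <- length(a); m <- length(b)
  pe <- function(x, y) {
    if ((x == "G" && y == "C") || (x == "C" && y == "G")) return(params$e_gc)
    if ((x == "A" && y == "T") || (x == "T" && y == "A")) return(params$e_at)
    if ((x == "G" && y == "T") || (x == "T" && y == "G")) return(params$e_gt)
    NA_real_
  }
  gapcost <- function(di, dj) min(di, dj) * params$mismatch +
    abs(di - dj) * params$bulge
  best <- matrix(Inf, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    e <- pe(a[i], b[j])
    if (is.na(e)) next
    pred <- 0
    if (i > 1 && j > 1) {
      for (ii in seq_len(i - 1L)) for (jj in seq_len(j - 1L)) {
        if (is.finite(best[ii, jj])) {
          pred <- min(pred, best[ii, jj] + gapcost(i - ii - 1L, j - jj - 1L))
        }
      }
    }
    best[i, j] <- e + pred
  }
  min(0, min(best))
}

# Exhaustive enumeration over all monotone pair sets (tiny instances only).
oracle_duplex_enum <- function(mirna, window, params = duplex_params()) {
  a <- strsplit(mirna, "")[[1]]
  b <- rev(strsplit(window, "")[[1]])
  n <- length(a); m <- length(b)
  pe <- function(x, y) {
    if ((x == "G" && y == "C") || (x == "C" && y == "G")) return(params$e_gc)
    if ((x == "A" && y == "T") || (x == "T" && y == "A")) return(params$e_at)
    if ((x == "G" && y == "T") || (x == "T" && y == "G")) return(params$e_gt)
    NA_real_
  }
  gapcost <- function(di, dj) min(di, dj) * params$mismatch +
    abs(di - dj) * params$bulge
  best <- 0
  # top-level: any first pair; recursion threads the previous pair's indices
  recurse2 <- function() {
    for (i in seq_len(n)) for (j in seq_len(m)) {
      e <- pe(a[i], b[j])
      if (is.na(e)) next
      if (e < best) best <<- e
      if (i < n && j < m) extend(i, j, e)
    }
  }
  extend <- function(pi, pj, acc) {
    for (i in (pi + 1L):n) for (j in (pj + 1L):m) {
      e <- pe(a[i], b[j])
      if (is.na(e)) next
      cost <- acc + gapcost(i - pi - 1L, j - pj - 1L) + e
      if (cost < best) best <<- cost
      if (i < n && j < m) extend(i, j, cost)
    }
  }
  recurse2()
  best
}

# Brute-force ORF enumeration on the periodic circle sequence truncated at
# four copies; start positions restricted to the first copy.
oracle_corfs <- function(s, min_aa = 10L) {
  L <- nchar(s); tot <- 4L * L
  big <- strrep(s, 5L)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (p in 0:(L - 1L)) {
    if (substr(big, p + 1L, p + 3L) != "ATG") next
    aa <- 0L; rolling <- TRUE; q <- p
    while (q + 3L <= tot) {
      cod <- substr(big, q + 1L, q + 3L)
      if (cod %in% stops) { rolling <- FALSE; break }
      aa <- aa + 1L; q <- q + 3L
    }
    if (aa <= min_aa) next
    pep <- translate_dna(substr(big, p + 1L, p + 3L * aa))
    res[[length(res) + 1L]] <- data.frame(
      start = p, aa_length = aa, peptide = pep,
      spans_junction = (p + 3L * aa) > L, rolling = rolling,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), aa_length = integer(0),
                      peptide = character(0), spans_junction = logical(0),
                      rolling = logical(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  df[!duplicated(paste(df$start %% L, df$peptide)), , drop = FALSE]
}

# Quadratic all-pairs overlap counter.
oracle_overlap_count <- function(f, r, mode) {
  if (mode == "events") {
    sum(vapply(seq_len(nrow(f)), function(i) {
      any(f$chrom[i] == r$chrom & f$start[i] < r$end & f$end[i] > r$start)
    }, logical(1)))
  } else {
    sum(vapply(seq_len(nrow(r)), function(i) {
      any(r$chrom[i] == f$chrom & r$start[i] < f$end & r$end[i] > f$start)
    }, logical(1)))
  }
}

# Brute-force BH: p_(i) * n / i, monotonized from the largest p down.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1L) for (i in (n - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
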