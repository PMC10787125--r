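#' Region set constructor
#'
#' A light wrapper around a data.frame of genomic intervals (0-based
#' half-open) used by the permutation framework.
#'
#' @param chrom,start,end interval columns.
#' @param label set label.
#' @return data.frame with class `region_set`.
#' @export
region_set <- function(chrom, start, end, label = "regions") {
  check_interval(start, end, label)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  attr(df, "label") <- label
  class(df) <- c("region_set", class(df))
  df
}

# Per-query any-overlap between interval sets on one chromosome.
# Subject intervals are merged (sorted, cummax) and each query checked
# against the covering run via findInterval; O((n+m) log m), vectorized.
overlaps_any_fast <- function(qs, qe, ss, se) {
  if (length(ss) == 0L || length(qs) == 0L) return(rep(FALSE, length(qs)))
  o <- order(ss)
  ss <- ss[o]; se <- cummax(se[o])
  keep <- c(TRUE, ss[-1L] > se[-length(se)])   # merge touching/overlapping
  ik <- which(keep)
  ms <- ss[ik]
  me <- se[c(ik[-1L] - 1L, length(se))]        # run end = cummax at run tail
  # last merged interval starting before the query end
  j <- findInterval(qe - 1L, ms)
  j > 0L & me[pmax(j, 1L)] > qs
}

split_overlaps_any <- function(q, s) {
  out <- rep(FALSE, nrow(q))
  for (ch in unique(q$chrom)) {
    qi <- which(q$chrom == ch)
    si <- s$chrom == ch
    out[qi] <- overlaps_any_fast(q$start[qi], q$end[qi],
                                 s$start[si], s$end[si])
  }
  out
}

#' Count feature/region overlaps
#'
#' `mode = "events"` counts features overlapping at least one region (each
#' feature once); `mode = "regions"` counts regions containing at least one
#' feature.
#'
#' @param features,regions [region_set()]s (or plain data.frames with
#'   `chrom`, `start`, `end`).
#' @param mode counting mode.
#' @return integer count.
#' @export
overlap_count <- function(features, regions, mode = c("events", "regions")) {
  mode <- match.arg(mode)
  if (nrow(features) == 0L || nrow(regions) == 0L) return(0L)
  if (mode == "events") sum(split_overlaps_any(features, regions))
  else sum(split_overlaps_any(regions, features))
}

#' Draw random transcript segments
#'
#' Emulates the null of the enrichment test: `k` segments placed uniformly
#' within transcripts that overlap no excluded region, with lengths sampled
#' (with replacement) from the observed length pool. Deterministic given the
#' RNG state.
#'
#' @param universe list of [transcript_model]s.
#' @param exclude [region_set()] of regions whose transcripts are ineligible
#'   (e.g. circRNA-producing loci); `NULL` or zero rows for no exclusion.
#' @param k number of segments.
#' @param length_pool integer vector of segment lengths to sample from.
#' @param max_tries bounded redraw rounds before failing.
#' @return [region_set()] of `k` segments.
#' @export
draw_random_segments <- function(universe, exclude, k, length_pool,
                                 max_tries = 50L) {
  if (k == 0L) return(region_set(character(0), integer(0), integer(0),
                                 "random"))
  elig <- eligible_transcripts(universe, exclude)
  if (length(elig) == 0L) cl_stop("UniverseExhausted",
                                  "no eligible transcripts")
  tx_chrom <- vapply(elig, `[[`, character(1), "chrom")
  tx_start <- vapply(elig, function(m) as.integer(m$start), integer(1))
  tx_span <- vapply(elig, function(m) as.integer(m$end - m$start), integer(1))
  len <- integer(k); ti <- integer(k)
  todo <- seq_len(k)
  for (round in seq_len(max_tries)) {
    len[todo] <- length_pool[sample.int(length(length_pool), length(todo),
                                        replace = TRUE)]
    ti[todo] <- sample.int(length(elig), length(todo), replace = TRUE)
    todo <- todo[tx_span[ti[todo]] < len[todo]]
    if (length(todo) == 0L) break
  }
  if (length(todo) > 0L) {
    cl_stop("UniverseExhausted", "could not place %d segment(s) after %d tries",
            length(todo), max_tries)
  }
  slack <- tx_span[ti] - len
  start <- tx_start[ti] + as.integer(floor(stats::runif(k) * (slack + 1)))
  region_set(tx_chrom[ti], start, start + len, "random")
}

eligible_transcripts <- function(universe, exclude) {
  if (is.null(exclude) || nrow(exclude) == 0L) return(universe)
  tx <- data.frame(chrom = vapply(universe, `[[`, character(1), "chrom"),
                   start = vapply(universe, `[[`, numeric(1), "start"),
                   end = vapply(universe, `[[`, numeric(1), "end"),
                   stringsAsFactors = FALSE)
  universe[!split_overlaps_any(tx, exclude)]
}

#' Permutation enrichment of features in target regions
#'
#' Observed overlap count of features in the target regions is compared with
#' counts in `n_perm` draws of equally many random transcript segments
#' (lengths matched to the targets). Reports permutation mean/sd, a z score
#' and the add-one empirical p-value
#' `(1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param features feature [region_set()] (e.g. AS events, R-loops).
#' @param target_regions target [region_set()] (e.g. ecircRNA transcribed
#'   regions).
#' @param universe list of [transcript_model]s to draw random segments from.
#' @param n_perm number of permutations.
#' @param mode overlap counting mode, see [overlap_count()].
#' @param exclude regions whose transcripts are ineligible for the null;
#'   defaults to the target regions themselves ("transcribed regions
#'   without circRNAs"); pass `NULL` for no exclusion.
#' @param fixed_length if not `NULL`, use this single segment length instead
#'   of the target length pool.
#' @return list with `observed`, `perm_mean`, `perm_sd`, `z`, `p_empirical`,
#'   `n_perm`, `degenerate` (sd == 0 guard) and the per-permutation
#'   `perm_counts`.
#' @export
enrichment_test <- function(features, target_regions, universe,
                            n_perm = 1000L, mode = c("events", "regions"),
                            exclude = target_regions, fixed_length = NULL) {
  mode <- match.arg(mode)
  observed <- overlap_count(features, target_regions, mode)
  k <- nrow(target_regions)
  pool <- if (is.null(fixed_length)) target_regions$end - target_regions$start
          else as.integer(fixed_length)
  elig <- eligible_transcripts(universe, exclude)
  perm_counts <- vapply(seq_len(n_perm), function(i) {
    seg <- draw_random_segments(elig, NULL, k, pool)
    overlap_count(features, seg, mode)
  }, numeric(1))
  mu <- mean(perm_counts)
  sdv <- stats::sd(perm_counts)
  degenerate <- is.na(sdv) || sdv == 0
  z <- if (degenerate) 0 else (observed - mu) / sdv
  p_emp <- (1 + sum(perm_counts >= observed)) / (n_perm + 1)
  list(observed = observed, perm_mean = mu,
       perm_sd = if (is.na(sdv)) 0 else sdv,
       z = z, p_empirical = p_emp, n_perm = n_perm,
       degenerate = degenerate, perm_counts = perm_counts)
}
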