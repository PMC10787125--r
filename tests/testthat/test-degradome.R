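test_that("build_5p_pileup distributes 1/n weights and conserves mass", {
  reads <- data.frame(
    read_id = c("u1", rep("m1", 4), "u2"),
    ref = c("t1", "t1", "t1", "t2", "t2", "t1"),
    start = c(100L, 10L, 50L, 5L, 30L, 100L),
    end = c(120L, 30L, 70L, 25L, 50L, 120L),
    strand = c("+", "+", "+", "+", "-", "+"),
    n_hits = c(1L, 4L, 4L, 4L, 4L, 1L))
  reads$five_prime <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  piles <- build_5p_pileup(reads, c(t1 = 200L, t2 = 100L))
  expect_equal(piles[["t1:+"]]$weights[101], 2.0)   # two unique reads at 100
  expect_equal(piles[["t1:+"]]$weights[11], 0.25)
  expect_equal(piles[["t2:-"]]$weights[50], 0.25)   # strand kept separate
  total <- sum(vapply(piles, function(p) sum(p$weights), numeric(1)))
  expect_equal(total, 3.0, tolerance = 1e-12)       # 3 distinct reads
  bad <- reads; bad$five_prime[1] <- 500L
  expect_error(build_5p_pileup(bad, c(t1 = 200L, t2 = 100L)),
               class = "PositionOutOfRange")
})

test_that("binomial_peak_pvalue matches closed forms and the sum oracle", {
  expect_equal(binomial_peak_pvalue(1, 1, 0.5), 0.5)
  expect_equal(binomial_peak_pvalue(10, 10, 0.3), 0.3^10)
  expect_equal(binomial_peak_pvalue(0, 5, 0.2), 1)
  expect_equal(binomial_peak_pvalue(6, 10, 0.01),
               oracle_binom_tail(6, 10, 0.01), tolerance = 1e-12)
  expect_error(binomial_peak_pvalue(5, 4, 0.5), class = "InvalidParameters")
  expect_error(binomial_peak_pvalue(1, 1, 0), class = "InvalidParameters")
  # monotone non-increasing in k
  for (p0 in c(1 / 21, 0.01, 0.5)) {
    pv <- vapply(0:30, binomial_peak_pvalue, numeric(1), N = 30, p0 = p0)
    expect_true(all(diff(pv) <= 1e-15))
  }
})

test_that("call_degradome_peaks enforces both thresholds with truncation", {
  w <- numeric(200)
  w[100] <- 6; w[c(95, 105)] <- c(2, 2)     # fraction 0.6 in its window
  w[150] <- 1; w[c(145, 155)] <- c(3, 3)    # fraction 1/7 < 0.5
  pile <- list(ref = "t", strand = "+", length = 200L, weights = w)
  pk <- call_degradome_peaks(pile)
  expect_identical(pk$pos, 99L)
  expect_equal(pk$fraction, 0.6)
  expect_equal(pk$p_value, oracle_binom_tail(6, sum(w), 1 / 200))
  # uniform pileup: max fraction 1/21, no peaks
  flat <- list(ref = "t", strand = "+", length = 100L,
               weights = rep(1, 100))
  expect_equal(nrow(call_degradome_peaks(flat)), 0)
  # edge position: window truncated, denominator restricted
  w2 <- numeric(50); w2[1] <- 3; w2[8] <- 2
  pile2 <- list(ref = "t", strand = "+", length = 50L, weights = w2)
  pk2 <- call_degradome_peaks(pile2, alpha = 1)
  expect_equal(pk2$window_total[pk2$pos == 0L], 5)   # positions 0..10 only
  expect_error(call_degradome_peaks(list(ref = "t", strand = "+",
                                         length = 10L,
                                         weights = numeric(10))),
               class = "EmptyPileup")
})

test_that("peak caller equals the brute-force evaluator (both null modes)", {
  set.seed(31)
  for (rep in 1:30) {
    L <- sample(30:500, 1)
    w <- numeric(L)
    nz <- sample(L, sample(3:30, 1))
    w[nz] <- round(rexp(length(nz), 1 / 3), 2)
    w[sample(L, 1)] <- sample(5:50, 1)
    pile <- list(ref = "t", strand = "+", length = L, weights = w)
    for (nm in c("transcript", "window")) {
      got <- call_degradome_peaks(pile, null_mode = nm)
      want <- oracle_peaks(pile, null_mode = nm)
      expect_identical(got$pos, want$pos)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
      # every emitted peak satisfies the printed thresholds
      expect_true(all(got$fraction >= 0.5))
      expect_true(all(got$p_value <= 0.05))
    }
  }
})

test_that("locate_peak_vs_circ is strand aware", {
  circ_p <- circ_rna("cp", "chr1", 100, 200, "+")
  circ_m <- circ_rna("cm", "chr1", 100, 200, "-")
  expect_identical(locate_peak_vs_circ(150, circ_p), "within")
  expect_identical(locate_peak_vs_circ(50, circ_p), "upstream")
  expect_identical(locate_peak_vs_circ(250, circ_p), "downstream")
  expect_identical(locate_peak_vs_circ(250, circ_m), "upstream")
  expect_identical(locate_peak_vs_circ(50, circ_m), "downstream")
  expect_identical(locate_peak_vs_circ(100, circ_m), "within")
  expect_error(locate_peak_vs_circ(50, circ_p, chrom = "chr2"),
               class = "ChromMismatch")
})

test_that("junction reference follows the flank rule and is periodic", {
  set.seed(41)
  genome <- c(chr1 = random_dna_str(400))
  circ <- circ_rna("c1", "chr1", 50, 250, "+")      # L = 200
  ref <- build_junction_reference(circ, genome)
  S <- circ_spliced_seq(circ, genome)
  expect_equal(nchar(ref$seq), 100)
  expect_equal(ref$junction_offset, 50)
  expect_identical(ref$seq, paste0(substr(S, 151, 200), substr(S, 1, 50)))
  # short circle: f = floor(L/2)
  circ2 <- circ_rna("c2", "chr1", 50, 110, "+")     # L = 60
  ref2 <- build_junction_reference(circ2, genome)
  expect_equal(ref2$junction_offset, 30)
  expect_equal(nchar(ref2$seq), 60)
  # periodicity: ref read base-by-base equals the periodic extension of S
  for (i in seq_len(nchar(ref$seq))) {
    per_idx <- (200 - 50 + i - 1) %% 200
    expect_identical(substr(ref$seq, i, i),
                     substr(S, per_idx + 1, per_idx + 1))
  }
})

test_that("junction mapping: overhang and mismatch rules, leftmost tie-break", {
  set.seed(43)
  genome <- c(chr1 = random_dna_str(400))
  circ <- circ_rna("c1", "chr1", 50, 250, "+")
  ref <- build_junction_reference(circ, genome)
  refs <- list(ref)
  # read = ref[46..65] (1-based): overhangs 5 and 15
  r <- setNames(substr(ref$seq, 46, 65), "ok")
  hits <- map_junction_spanning_reads(r, refs)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 45)
  expect_equal(hits$overhang_left, 5)
  expect_equal(hits$overhang_right, 15)
  # entirely left of the junction: no hit
  r2 <- setNames(substr(ref$seq, 1, 30), "left")
  expect_equal(nrow(map_junction_spanning_reads(r2, refs)), 0)
  # two mismatches rejected at max_mismatch = 1
  r3 <- r
  substr(r3, 8, 9) <- if (substr(r3, 8, 9) == "AA") "CC" else "AA"
  expect_equal(nrow(map_junction_spanning_reads(setNames(r3, "mm2"), refs)), 0)
  # one mismatch accepted
  r4 <- r
  substr(r4, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                              substr(r4, 8, 8))[1]
  h4 <- map_junction_spanning_reads(setNames(r4, "mm1"), refs)
  expect_equal(h4$mismatches, 1)
  expect_error(map_junction_spanning_reads(setNames("ACGTACG", "tiny"), refs),
               class = "ReadTooShort")
})

test_that("simulated junction reads: full recall, linear locus zero hits", {
  cfg <- sim_config(seed = 171, n_genes = 12, n_ecirc = 6, n_cirna = 2,
                    junction_read_count = 15L)
  sim <- make_toy_genome(cfg)
  pc <- plant_circrnas(sim, cfg)
  linear_ext <- vapply(names(pc$circs), function(id) {
    cr <- pc$circs[[id]]
    chrom <- sim$genome[[cr$chrom]]
    if (cr$strand == "+") substr(chrom, cr$end + 1L, cr$end + 50L)
    else revcomp(substr(chrom, max(1L, cr$start - 49L), cr$start))
  }, character(1))
  jr <- simulate_junction_reads(pc$spliced, linear_ext, cfg)
  refs <- lapply(pc$circs, build_junction_reference, genome = sim$genome)
  hits <- map_junction_spanning_reads(jr$junction_reads, refs)
  # every simulated read is recovered on its own circle
  own <- paste(hits$read_id, hits$circ_id) %in%
    paste(jr$truth$read_id, jr$truth$circ_id)
  expect_true(all(jr$truth$read_id %in% hits$read_id[own]))
  expect_true(all(hits$overhang_left >= 5 & hits$overhang_right >= 5))
  lhits <- map_junction_spanning_reads(jr$linear_reads, refs)
  expect_equal(nrow(lhits), 0)
})
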