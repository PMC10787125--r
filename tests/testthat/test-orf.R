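test_that("rolling_circle_seq is exact 4x concatenation", {
  expect_identical(rolling_circle_seq("ACG"), "ACGACGACGACG")
  s <- random_dna_str(37)
  out <- rolling_circle_seq(s)
  expect_equal(nchar(out), 4 * 37)
  for (i in sample(seq_len(4 * 37), 20)) {
    expect_identical(substr(out, i, i),
                     substr(s, ((i - 1) %% 37) + 1, ((i - 1) %% 37) + 1))
  }
  expect_error(rolling_circle_seq(""), class = "EmptySequence")
})

test_that("short ORFs are filtered by the strict > 10 aa rule", {
  # MK then stop: 2 aa, well under the threshold
  expect_equal(nrow(find_corfs("ATGAAATAA")), 0)
  # exactly 10 aa is still filtered; 11 aa passes
  mk <- function(aa) paste0("ATG", strrep("GCT", aa - 1), "TAA",
                            strrep("C", 50))
  expect_equal(nrow(find_corfs(mk(10))), 0)
  orfs <- find_corfs(mk(11))
  expect_true(any(orfs$aa_length == 11 & !orfs$rolling))
})

test_that("designed junction-crossing circle yields one spanning cORF", {
  # 60-nt circle: ORF starts near the end of the circle and finds its stop
  # only after wrapping the junction.
  circ <- paste0(strrep("C", 6), "TAA", strrep("C", 36), "ATG",
                 strrep("GCA", 4))  # stop at 6..8, in frame iff (6-45) %% 3 == 0
  expect_equal((6 - 45) %% 3, 0)
  orfs <- find_corfs(paste0(circ), min_aa = 5)
  span <- orfs[orfs$start == 45, ]
  expect_equal(nrow(span), 1)
  expect_true(span$spans_junction)
  expect_false(span$rolling)
  # codons: ATG + GCA x4 + (wrap) CCC CCC, stop at 66 -> 7 aa
  expect_equal(span$aa_length, 7)
})

test_that("33-nt circle without in-frame stop gives one rolling cORF", {
  circ <- paste0("ATG", strrep("GCA", 10))   # 33 nt
  orfs <- find_corfs(circ)
  expect_equal(nrow(orfs), 1)
  expect_true(orfs$rolling)
  expect_true(orfs$spans_junction)
  expect_equal(orfs$aa_length, 44)           # truncated at 4 copies
})

test_that("find_corfs equals the periodic brute-force oracle", {
  set.seed(61)
  for (rep in 1:120) {
    L <- sample(30:300, 1)
    s <- random_dna_str(L)
    got <- find_corfs(s)
    want <- oracle_corfs(s)
    got <- got[order(got$start), ]
    want <- want[order(want$start), ]
    expect_equal(got$start, want$start)
    expect_equal(got$aa_length, want$aa_length)
    expect_identical(got$peptide, want$peptide)
    expect_identical(got$spans_junction, want$spans_junction)
    expect_identical(got$rolling, want$rolling)
    # peptide length cap and re-translation
    expect_true(all(got$aa_length <= ceiling(4 * L / 3)))
    for (i in seq_len(nrow(got))) {
      nt <- periodic_substr(s, got$start[i], 3L * got$aa_length[i])
      expect_identical(translate_dna(nt), got$peptide[i])
    }
  }
})

test_that("find_corfs output is rotation invariant (as peptide sets)", {
  set.seed(62)
  for (rep in 1:25) {
    L <- sample(30:150, 1)
    s <- random_dna_str(L)
    r <- sample(L, 1)
    s_rot <- paste0(substr(s, r + 1, L), substr(s, 1, r))
    # rolling peptides are truncated at 4 copies, so their tail length is
    # rotation bookkeeping; compare them over one frame cycle only
    cyc <- L %/% ifelse(L %% 3 == 0, 3, 1)
    key <- function(d) sort(paste(ifelse(d$rolling,
                                         substr(d$peptide, 1, cyc),
                                         d$peptide), d$rolling))
    expect_identical(key(find_corfs(s)), key(find_corfs(s_rot)))
  }
})

test_that("uORF/dORF classification respects CDS boundaries", {
  utr5 <- paste0("CC", "ATG", strrep("GCT", 12), "TAA", "CC")   # M+12 aa uORF
  cds <- paste0("ATG", strrep("AAA", 20), "TAA")
  utr3 <- paste0("G", "ATG", strrep("TCT", 15), "TGA", "AA")    # M+15 aa dORF
  tx <- paste0(utr5, cds, utr3)
  cds_start <- nchar(utr5)
  cds_end <- cds_start + nchar(cds)
  orfs <- find_uorfs_dorfs(tx, cds_start, cds_end)
  expect_identical(sort(unique(orfs$kind)), c("dORF", "pORF", "uORF"))
  expect_equal(orfs$aa_length[orfs$kind == "uORF"], 13)
  expect_equal(orfs$aa_length[orfs$kind == "dORF"], 16)
  expect_equal(orfs$aa_length[orfs$kind == "pORF"], 21)  # M + 20 aa
  expect_equal(orfs$start[orfs$kind == "pORF"], cds_start)
  expect_error(find_uorfs_dorfs(tx, 10, 5), class = "InvalidCDS")
})

test_that("ORFs straddling the CDS are excluded and counted", {
  # ORF starting in the 5' UTR whose stop lies inside the CDS
  tx <- paste0("A", "ATG", strrep("GGG", 15),          # no stop before CDS
               strrep("AAA", 10), "TAA", strrep("C", 30))
  cds_start <- 20L   # inside the long ORF
  cds_end <- cds_start + 60L
  orfs <- find_uorfs_dorfs(tx, cds_start, cds_end, min_aa = 5)
  expect_false(any(orfs$kind %in% c("uORF", "dORF") & orfs$start == 1))
  expect_gte(attr(orfs, "n_overlapping"), 1)
})

test_that("unique_peptide_filter drops shared peptides, keeps supported ORFs", {
  orfs <- c(a = "MKLVNNPQRSTWEEF", b = "MHHLVNNPQRSGGG", c = "MCCCCCDDDDD")
  # "LVNNPQRS" occurs in a and b; "WEEF" only in a; "CCDDD" only in c
  res <- unique_peptide_filter(c("LVNNPQRS", "WEEF", "CCDDD"), orfs)
  expect_identical(sort(res$supported_orfs), c("a", "c"))
  expect_identical(res$dropped_peptides, "LVNNPQRS")
  # ORF b has only a shared peptide: not retained
  expect_false("b" %in% res$supported_orfs)
  # never retain an ORF with zero surviving peptides
  expect_true(all(res$supported_orfs %in% res$matches$orf_id))
})

test_that("simulated peptide tables behave as constructed", {
  cfg <- sim_config(seed = 77)
  orfs <- c(o1 = "MAAAAKLWWPQR", o2 = "MCCCCKLYYPQR", o3 = "MDDDDHHGGFFE",
            o4 = "MEEEEHHGGFFK")
  sp <- simulate_peptides(orfs, cfg, n_supported = 2L, n_decoys = 2L)
  res <- unique_peptide_filter(sp$peptides, orfs)
  expect_identical(sort(res$supported_orfs), sort(sp$truth$supported_orfs))
  expect_true(all(sp$truth$decoys %in% res$dropped_peptides))
  sp2 <- simulate_peptides(orfs, cfg, n_supported = 2L, n_decoys = 2L)
  expect_identical(sp, sp2)                 # seed determinism
})
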