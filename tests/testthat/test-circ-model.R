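models <- toy_models()

test_that("classify_circ_type follows exon/intron/intergenic precedence", {
  # identical to exon 2 of txA
  expect_identical(classify_circ_type(
    circ_rna("c1", "chr1", 30, 40, "+"), models), "ecircRNA")
  # strictly inside intron 1 of txA
  expect_identical(classify_circ_type(
    circ_rna("c2", "chr1", 22, 28, "+"), models), "ciRNA")
  # whole intron counts as contained
  expect_identical(classify_circ_type(
    circ_rna("c3", "chr1", 20, 30, "+"), models), "ciRNA")
  # no models on this chromosome
  expect_identical(classify_circ_type(
    circ_rna("c4", "chr9", 10, 40, "+"), models), "intergenic")
  # exon overlap on the wrong strand does not count
  expect_identical(classify_circ_type(
    circ_rna("c5", "chr1", 30, 40, "-"), models), "intergenic")
  # exon overlap wins over intron containment (straddles boundary)
  expect_identical(classify_circ_type(
    circ_rna("c6", "chr1", 25, 35, "+"), models), "ecircRNA")
})

test_that("alternative back-splicing labels follow the boundary rules", {
  mk <- function(id, s, e, strand = "+",
                 exons = data.frame(start = s, end = e)) {
    circ_rna(id, "chr1", s, e, strand, exons)
  }
  # + strand: donor = genomic end
  lab <- classify_alt_backsplicing(list(mk("a", 100, 500), mk("b", 200, 500)))
  expect_identical(lab$label, "A5BS")
  lab <- classify_alt_backsplicing(list(mk("a", 100, 500), mk("b", 100, 700)))
  expect_identical(lab$label, "A3BS")
  # - strand: donor = genomic start, so shared start = A5BS
  lab <- classify_alt_backsplicing(list(mk("a", 100, 500, "-"),
                                        mk("b", 100, 700, "-")))
  expect_identical(lab$label, "A5BS")
  # MIC: partial overlap, mutually exclusive exons
  a <- mk("a", 100, 500, exons = data.frame(start = c(100, 300),
                                            end = c(200, 500)))
  b <- mk("b", 300, 700, exons = data.frame(start = c(300, 600),
                                            end = c(500, 700)))
  lab <- classify_alt_backsplicing(list(a, b))
  expect_identical(lab$label, "MIC")
  # containment is not MIC
  lab <- classify_alt_backsplicing(list(mk("a", 100, 700), mk("b", 200, 500)))
  expect_equal(nrow(lab), 0)
  # mixed strands error
  expect_error(classify_alt_backsplicing(list(mk("a", 1, 5), mk("b", 1, 9, "-"))),
               class = "StrandMismatch")
})

test_that("each pair gets at most one label and labels are order-symmetric", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    circs <- lapply(seq_len(n), function(i) {
      s <- sample(seq(0, 400, by = 100), 1)
      e <- s + sample(seq(100, 400, by = 100), 1)
      nex <- sample(1:2, 1)
      exs <- if (nex == 1) data.frame(start = s, end = e)
             else data.frame(start = c(s, e - 50), end = c(s + 50, e))
      circ_rna(paste0("c", i), "chr1", s, e, "+", exs)
    })
    lab <- classify_alt_backsplicing(circs)
    if (nrow(lab) > 0) {
      expect_false(any(duplicated(paste(lab$circ_a, lab$circ_b))))
    }
    lab_rev <- classify_alt_backsplicing(rev(circs))
    key <- function(d) sort(paste(pmin(d$circ_a, d$circ_b),
                                  pmax(d$circ_a, d$circ_b), d$label))
    expect_identical(key(lab), key(lab_rev))
  }
})

test_that("internal AS classification distinguishes the four types", {
  mk <- function(id, exons, strand = "+") {
    circ_rna(id, "chr1", min(exons$start), max(exons$end), strand, exons)
  }
  e1 <- c(0, 100); e2 <- c(200, 300); e3 <- c(400, 500)
  chain <- function(...) {
    m <- do.call(rbind, list(...))
    data.frame(start = m[, 1], end = m[, 2])
  }
  # exon skipping
  lab <- classify_internal_as(list(mk("a", chain(e1, e2, e3)),
                                   mk("b", chain(e1, e3))))
  expect_identical(lab$label, "ExonS")
  # intron retention: one chain continuous across the e1-e2 intron
  lab <- classify_internal_as(list(mk("a", chain(e1, e2, e3)),
                                   mk("b", chain(c(0, 300), e3))))
  expect_identical(lab$label, "IntronR")
  # acceptor (exon start) shift on + strand = A3SS
  lab <- classify_internal_as(list(mk("a", chain(e1, e2, e3)),
                                   mk("b", chain(e1, c(212, 300), e3))))
  expect_identical(lab$label, "A3SS")
  # same shift on - strand = A5SS
  lab <- classify_internal_as(list(mk("a", chain(e1, e2, e3), "-"),
                                   mk("b", chain(e1, c(212, 300), e3), "-")))
  expect_identical(lab$label, "A5SS")
  # donor (exon end) shift on + strand = A5SS
  lab <- classify_internal_as(list(mk("a", chain(e1, e2, e3)),
                                   mk("b", chain(e1, c(200, 288), e3))))
  expect_identical(lab$label, "A5SS")
  # boundary mismatch errors
  expect_error(classify_internal_as(list(mk("a", chain(e1, e3)),
                                         mk("b", chain(e2, e3)))),
               class = "BoundaryMismatch")
})

test_that("rpm_normalize implements count / (total/1e6), is linear, keeps 0", {
  counts <- cbind(s1 = c(50, 0, 10), s2 = c(5, 2, 0))
  rpm <- rpm_normalize(counts, c(1e6, 2e6))
  expect_equal(rpm[, "s1"], c(50, 0, 10))
  expect_equal(rpm[, "s2"], c(2.5, 1, 0))
  expect_equal(rpm_normalize(counts * 3, c(1e6, 2e6)), unclass(rpm) * 3,
               ignore_attr = TRUE)
  expect_error(rpm_normalize(counts, c(0, 1e6)), class = "ZeroLibrary")
})

test_that("fold change is reciprocal and exact without zeros", {
  expect_equal(fold_change(400, 100), 4)
  set.seed(5)
  a <- c(0, runif(50, 0, 100)); b <- c(runif(50, 0, 100), 0)
  expect_true(all(abs(fold_change(a, b) * fold_change(b, a) - 1) < 1e-12))
})

test_that("bh_adjust equals the brute-force BH oracle", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.5)),
               c(0.004, 0.04, 0.04, 0.5))
  set.seed(8)
  for (rep in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    # monotone after sorting by p
    o <- order(p)
    expect_true(all(diff(bh_adjust(p)[o]) >= -1e-15))
  }
})

test_that("differential_circrnas applies the triple cutoff", {
  trt <- c(a = 100, b = 400, c = 100, d = 3)
  ctl <- c(a = 100, b = 100, c = 800, d = 4)
  de <- differential_circrnas(trt, ctl, 1e6, 1e6)
  expect_equal(de$fold_change[de$id == "b"], 4)
  expect_identical(de$direction[de$id == "a"], "ns")
  expect_identical(de$direction[de$id == "b"], "up")
  expect_identical(de$direction[de$id == "c"], "down")
  expect_identical(de$direction[de$id == "d"], "ns")
  # p-value definition: two-sided exact binomial with p0 = N1/(N1+N2)
  expect_equal(de$p_value[de$id == "b"],
               binom.test(400, 500, 0.5)$p.value)
  expect_error(differential_circrnas(trt, ctl, 0, 1e6),
               class = "ZeroLibrary")
})

test_that("pearson_profile matches cor and flags |r| >= 0.5", {
  expect_equal(pearson_profile(c(1, 2, 3), c(2, 4, 6)),
               list(r = 1, high = TRUE))
  expect_equal(pearson_profile(c(1, 2, 3), c(3, 2, 1)),
               list(r = -1, high = TRUE))
  expect_error(pearson_profile(c(1, 2, 3), c(2, 2, 2)),
               class = "ConstantVector")
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_profile(x, y)$r, cor(x, y))
})
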