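#' Simulation configuration
#'
#' Defaults state the synthetic world used across the test surface: gene
#' and exon sizes typical of a compact plant genome, 21-nt miRNAs, 200
#' degradome reads per planted cleavage site over a uniform background of
#' 0.05 reads/nt, 30-nt reads, and a tenth of background reads
#' multi-mapping at 2-4 loci.
#'
#' @param seed mandatory RNG seed (integer).
#' @param n_genes number of genes on the toy chromosome.
#' @param exons_per_gene integer range (min, max).
#' @param exon_len,intron_len,intergenic_len length ranges in nt.
#' @param n_ecirc,n_cirna circRNAs to plant.
#' @param n_mirna number of mature miRNAs.
#' @param mirna_len miRNA length.
#' @param n_sites planted cleavage sites.
#' @param signal_reads degradome reads per planted site.
#' @param background_rate background degradome reads per transcript nt.
#' @param read_len degradome/junction read length.
#' @param junction_read_count junction-spanning reads per circle.
#' @param multimap_frac fraction of background reads reported at 2-4 loci.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(seed, n_genes = 20L, exons_per_gene = c(2L, 5L),
                       exon_len = c(80L, 300L), intron_len = c(60L, 200L),
                       intergenic_len = c(100L, 400L),
                       n_ecirc = 5L, n_cirna = 3L,
                       n_mirna = 10L, mirna_len = 21L,
                       n_sites = 10L, signal_reads = 200L,
                       background_rate = 0.05, read_len = 30L,
                       junction_read_count = 10L, multimap_frac = 0.1) {
  if (missing(seed)) cl_stop("ConfigInvalid", "seed is mandatory")
  cfg <- as.list(environment())
  bad <- vapply(cfg[c("n_genes", "n_ecirc", "n_cirna", "n_mirna", "n_sites",
                      "signal_reads", "read_len", "junction_read_count")],
                function(x) any(x < 0), logical(1))
  if (any(bad) || background_rate < 0 || multimap_frac < 0) {
    cl_stop("ConfigInvalid", "counts and rates must be >= 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a toy genome with gene models
#'
#' One random chromosome carrying `n_genes` multi-exon genes separated by
#' intergenic spacers; deterministic per seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named character), `models` (named list of
#'   [transcript_model]) and `truth` (gene table).
#' @export
make_toy_genome <- function(cfg) {
  set.seed(cfg$seed)
  pos <- 0L
  models <- list()
  for (g in seq_len(cfg$n_genes)) {
    pos <- pos + runif_int(1L, cfg$intergenic_len)
    k <- runif_int(1L, cfg$exons_per_gene)
    ex_lens <- runif_int(k, cfg$exon_len)
    in_lens <- if (k > 1L) runif_int(k - 1L, cfg$intron_len) else integer(0)
    starts <- integer(k); ends <- integer(k)
    p <- pos
    for (i in seq_len(k)) {
      starts[i] <- p
      ends[i] <- p + ex_lens[i]
      p <- ends[i] + if (i < k) in_lens[i] else 0L
    }
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%02d", g)
    tid <- sprintf("tx%02d", g)
    models[[tid]] <- transcript_model(gid, tid, "chr1", strand,
                                      data.frame(start = starts, end = ends))
    pos <- p
  }
  total <- pos + runif_int(1L, cfg$intergenic_len)
  genome <- c(chr1 = random_dna(total))
  truth <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    transcript_id = names(models),
    strand = vapply(models, `[[`, character(1), "strand"),
    n_exons = vapply(models, function(m) nrow(m$exons), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(genome = genome, models = models, truth = truth)
}

#' Write transcript models as GFF3
#'
#' @param models named list of [transcript_model].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$chrom, m$start + 1L, m$end, m$strand, m$gene_id),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$chrom, m$start + 1L, m$end, m$strand, m$transcript_id,
              m$gene_id),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              m$chrom, m$exons$start + 1L, m$exons$end, m$strand,
              m$transcript_id, seq_len(nrow(m$exons)), m$transcript_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Plant circRNAs into a toy genome
#'
#' ecircRNAs are built from runs of consecutive exons of randomly chosen
#' transcripts; ciRNAs occupy single introns. BED12 blocks follow the chosen
#' exons.
#'
#' @param sim result of [make_toy_genome()].
#' @param cfg a [sim_config()].
#' @return list with `circs` (named list of [circ_rna]), `spliced` (named
#'   character of circle sequences), `truth` data.frame.
#' @export
plant_circrnas <- function(sim, cfg) {
  set.seed(cfg$seed + 1L)
  models <- sim$models
  circs <- list(); truth <- list()
  n <- 0L
  multi <- models[vapply(models, function(m) nrow(m$exons) >= 1L, logical(1))]
  for (i in seq_len(cfg$n_ecirc)) {
    m <- multi[[sample.int(length(multi), 1L)]]
    k <- nrow(m$exons)
    i1 <- sample.int(k, 1L)
    i2 <- min(k, i1 + sample.int(min(3L, k - i1 + 1L), 1L) - 1L)
    ex <- m$exons[i1:i2, , drop = FALSE]
    n <- n + 1L
    id <- sprintf("circ%02d", n)
    circs[[id]] <- circ_rna(id, m$chrom, min(ex$start), max(ex$end),
                            m$strand, ex,
                            junction_reads = sample(5:80, 1L),
                            host_gene = m$gene_id, circ_type = "ecircRNA")
    truth[[id]] <- data.frame(circ_id = id, type = "ecircRNA",
                              host = m$transcript_id,
                              stringsAsFactors = FALSE)
  }
  intronic <- models[vapply(models, function(m) nrow(m$exons) >= 2L,
                            logical(1))]
  for (i in seq_len(cfg$n_cirna)) {
    m <- intronic[[sample.int(length(intronic), 1L)]]
    k <- nrow(m$exons)
    w <- sample.int(k - 1L, 1L)
    istart <- m$exons$end[w]; iend <- m$exons$start[w + 1L]
    n <- n + 1L
    id <- sprintf("circ%02d", n)
    circs[[id]] <- circ_rna(id, m$chrom, istart, iend, m$strand,
                            junction_reads = sample(5:80, 1L),
                            host_gene = m$gene_id, circ_type = "ciRNA")
    truth[[id]] <- data.frame(circ_id = id, type = "ciRNA",
                              host = m$transcript_id,
                              stringsAsFactors = FALSE)
  }
  spliced <- vapply(circs, circ_spliced_seq, character(1),
                    genome = sim$genome)
  list(circs = circs, spliced = spliced, truth = do.call(rbind, truth))
}

#' Generate random mature miRNAs
#'
#' @param cfg a [sim_config()].
#' @return named character vector of miRNA sequences (T alphabet).
#' @export
simulate_mirnas <- function(cfg) {
  set.seed(cfg$seed + 2L)
  setNames(vapply(seq_len(cfg$n_mirna), function(i) random_dna(cfg$mirna_len),
                  character(1)),
           sprintf("mir%02d", seq_len(cfg$n_mirna)))
}

#' Plant miRNA target sites into transcript sequences
#'
#' At each chosen site s, the reverse complement of a miRNA is embedded so
#' that the target base paired with miRNA position 10 sits exactly at s:
#' the predicted slice position of a perfect duplex then coincides with the
#' planted degradome peak.
#'
#' @param tx_seqs named character vector of transcript sequences.
#' @param mirnas named character vector of miRNAs.
#' @param cfg a [sim_config()].
#' @return list with `tx_seqs` (edited) and `truth` data.frame
#'   (`transcript`, `site`, `mirna`).
#' @export
plant_cleavage_sites <- function(tx_seqs, mirnas, cfg) {
  set.seed(cfg$seed + 3L)
  n <- nchar(mirnas[[1L]])
  truth <- list()
  margin <- 30L + n
  eligible <- names(tx_seqs)[nchar(tx_seqs) >= 2L * margin + cfg$read_len]
  txs <- sample(eligible, cfg$n_sites, replace = cfg$n_sites > length(eligible))
  for (i in seq_len(cfg$n_sites)) {
    tx <- txs[i]
    mir_id <- names(mirnas)[(i - 1L) %% length(mirnas) + 1L]
    mir <- mirnas[[mir_id]]
    L <- nchar(tx_seqs[[tx]])
    repeat {
      s <- sample(seq(margin, L - margin - cfg$read_len), 1L)
      prev <- vapply(truth, function(t)
        t$transcript == tx && abs(t$site - s) < 60L, logical(1))
      if (!any(prev)) break
    }
    a <- s - nchar(mir) + 10L                # 0-based embed start
    site_seq <- revcomp(mir)
    substr(tx_seqs[[tx]], a + 1L, a + nchar(mir)) <- site_seq
    truth[[i]] <- data.frame(transcript = tx, site = s, mirna = mir_id,
                             stringsAsFactors = FALSE)
  }
  list(tx_seqs = tx_seqs, truth = do.call(rbind, truth))
}

#' Simulate an aligned degradome library
#'
#' Signal reads start exactly at planted cleavage sites; background read 5'
#' ends fall uniformly at `background_rate` per nt; a configured fraction of
#' background reads multi-map at 2-4 loci with matching NH tags (weights
#' 1/n). Output is an already-aligned SAM in transcript space.
#'
#' @param tx_seqs named character vector of (edited) transcript sequences.
#' @param planted truth data.frame from [plant_cleavage_sites()] (may have
#'   zero rows).
#' @param cfg a [sim_config()].
#' @param path output SAM path.
#' @return list with `path`, `n_reads` (distinct simulated reads) and
#'   `records` data.frame.
#' @export
simulate_degradome <- function(tx_seqs, planted, cfg, path = tempfile(fileext = ".sam")) {
  set.seed(cfg$seed + 4L)
  rl <- cfg$read_len
  recs <- list()
  rid <- 0L
  n_reads <- 0L
  for (i in seq_len(NROW(planted))) {
    tx <- planted$transcript[i]; s <- planted$site[i]
    seq <- substr(tx_seqs[[tx]], s + 1L, s + rl)
    for (j in seq_len(cfg$signal_reads)) {
      rid <- rid + 1L; n_reads <- n_reads + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = sprintf("sig%06d", rid), ref = tx, pos = s,
        strand = "+", seq = seq, n_hits = 1L, stringsAsFactors = FALSE)
    }
  }
  for (tx in names(tx_seqs)) {
    L <- nchar(tx_seqs[[tx]])
    n_bg <- rbinom(1L, L, min(1, cfg$background_rate))
    if (n_bg == 0L) next
    pos <- sample.int(max(1L, L - rl), n_bg, replace = TRUE) - 1L
    for (p in pos) {
      rid <- rid + 1L; n_reads <- n_reads + 1L
      nh <- if (runif(1) < cfg$multimap_frac) sample(2:4, 1L) else 1L
      # report the read at nh loci (first = its origin), NH tag on each
      loci_tx <- c(tx, sample(names(tx_seqs), nh - 1L, replace = TRUE))
      for (h in seq_len(nh)) {
        ltx <- loci_tx[h]
        lp <- if (h == 1L) p else
          sample.int(max(1L, nchar(tx_seqs[[ltx]]) - rl), 1L) - 1L
        recs[[length(recs) + 1L]] <- data.frame(
          read_id = sprintf("bg%06d", rid), ref = ltx, pos = lp,
          strand = "+", seq = substr(tx_seqs[[ltx]], lp + 1L, lp + rl),
          n_hits = nh, stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(read_id = character(0), ref = character(0), pos = integer(0),
               strand = character(0), seq = character(0), n_hits = integer(0))
  write_sam(records, setNames(nchar(tx_seqs), names(tx_seqs)), path)
  list(path = path, n_reads = n_reads, records = records)
}

#' Simulate back-splice junction reads with a matched linear control
#'
#' Positive reads are substrings of the periodic circle sequence crossing
#' the back-splice point with at least `min_overhang` nt on each side.
#' Control reads are drawn uniformly from the *linear* sequence across the
#' same locus: the circle's terminal flank followed by the genomic sequence
#' that follows the back-splice donor.
#'
#' @param spliced named character of spliced circle sequences.
#' @param linear_ext named character: per circle, the linear continuation
#'   after the donor (>= flank nt).
#' @param cfg a [sim_config()].
#' @param min_overhang minimum junction overhang for positive reads.
#' @param flank junction flank (as in [build_junction_reference()]).
#' @return list with `junction_reads`, `linear_reads` (named character) and
#'   `truth` data.frame for the positives.
#' @export
simulate_junction_reads <- function(spliced, linear_ext, cfg,
                                    min_overhang = 5L, flank = 50L) {
  set.seed(cfg$seed + 5L)
  rl <- cfg$read_len
  jr <- character(0); lr <- character(0); truth <- list()
  for (id in names(spliced)) {
    S <- spliced[[id]]
    L <- nchar(S)
    f <- min(flank, L %/% 2L)
    if (rl > 2L * f) next
    for (k in seq_len(cfg$junction_read_count)) {
      off <- sample(seq(max(0L, f + min_overhang - rl), f - min_overhang), 1L)
      read <- periodic_substr(S, (L - f + off) %% L, rl)
      nm <- sprintf("%s_jr%03d", id, k)
      jr[nm] <- read
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = nm, circ_id = id, overhang_left = f - off,
        overhang_right = off + rl - f, stringsAsFactors = FALSE)
    }
    lin <- paste0(substr(S, L - f + 1L, L),
                  substr(linear_ext[[id]], 1L, f))
    for (k in seq_len(cfg$junction_read_count)) {
      st <- sample.int(nchar(lin) - rl + 1L, 1L) - 1L
      lr[sprintf("%s_lin%03d", id, k)] <- substr(lin, st + 1L, st + rl)
    }
  }
  list(junction_reads = jr, linear_reads = lr,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Simulate a proteomics peptide table
#'
#' Designated ORFs receive one peptide that occurs in no other ORF (drawn
#' from their unique 7-mers); decoy peptides shared between at least two
#' ORFs are added and must be dropped by [unique_peptide_filter()].
#'
#' @param orf_peptides named character vector: ORF id -> peptide.
#' @param cfg a [sim_config()].
#' @param n_supported how many ORFs to support with unique evidence.
#' @param n_decoys how many shared decoy peptides to insert.
#' @return list with `peptides` (character), `truth` (`supported_orfs`,
#'   `decoys`).
#' @export
simulate_peptides <- function(orf_peptides, cfg, n_supported = 3L,
                              n_decoys = 2L) {
  set.seed(cfg$seed + 6L)
  kmers_of <- function(p, k) {
    if (nchar(p) < k) return(character(0))
    unique(substring(p, seq_len(nchar(p) - k + 1L),
                     seq_len(nchar(p) - k + 1L) + k - 1L))
  }
  count_matches <- function(km) {
    sum(vapply(orf_peptides, function(o) grepl(km, o, fixed = TRUE),
               logical(1)))
  }
  unique_pep <- list()
  for (id in names(orf_peptides)) {
    for (km in kmers_of(orf_peptides[[id]], 7L)) {
      if (count_matches(km) == 1L) { unique_pep[[id]] <- km; break }
    }
  }
  avail <- names(unique_pep)
  supported <- avail[sample.int(length(avail), min(n_supported, length(avail)))]
  peptides <- unlist(unique_pep[supported], use.names = FALSE)
  decoys <- character(0)
  all3 <- unique(unlist(lapply(orf_peptides, kmers_of, k = 3L)))
  for (km in sample(all3)) {
    if (length(decoys) >= n_decoys) break
    if (count_matches(km) >= 2L) decoys <- c(decoys, km)
  }
  list(peptides = c(peptides, decoys),
       truth = list(supported_orfs = supported, decoys = decoys))
}

#' Run every simulator and write all fixture files
#'
#' Deterministic per seed: two runs with the same config give byte-identical
#' files.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return named list of file paths plus the in-memory `truth` objects.
#' @export
simulate_all <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(outdir, x)
  sim <- make_toy_genome(cfg)
  write_fasta(sim$genome, fp("genome.fa"))
  write_gff3(sim$models, fp("models.gff3"))

  pc <- plant_circrnas(sim, cfg)
  write_circ_table(pc$circs, fp("circs.bed"))
  write_fasta(pc$spliced, fp("circ_spliced.fa"))

  mirnas <- simulate_mirnas(cfg)
  write_fasta(mirnas, fp("mirnas.fa"))

  tx_seqs <- vapply(sim$models, spliced_seq, character(1),
                    genome = sim$genome)
  planted <- plant_cleavage_sites(tx_seqs, mirnas, cfg)
  write_fasta(planted$tx_seqs, fp("transcripts.fa"))
  deg <- simulate_degradome(planted$tx_seqs, planted$truth, cfg,
                            fp("degradome.sam"))

  linear_ext <- vapply(names(pc$circs), function(id) {
    cr <- pc$circs[[id]]
    chrom <- sim$genome[[cr$chrom]]
    if (cr$strand == "+") substr(chrom, cr$end + 1L, cr$end + 50L)
    else revcomp(substr(chrom, max(1L, cr$start - 49L), cr$start))
  }, character(1))
  jr <- simulate_junction_reads(pc$spliced, linear_ext, cfg)
  if (length(jr$junction_reads)) write_fasta(jr$junction_reads,
                                             fp("junction_reads.fa"))
  if (length(jr$linear_reads)) write_fasta(jr$linear_reads,
                                           fp("linear_reads.fa"))

  write.table(planted$truth, fp("truth_cleavage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pc$truth, fp("truth_circs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(genome = fp("genome.fa"), gff = fp("models.gff3"),
       circs = fp("circs.bed"), circ_fa = fp("circ_spliced.fa"),
       mirnas = fp("mirnas.fa"), transcripts = fp("transcripts.fa"),
       degradome = fp("degradome.sam"),
       junction_reads = fp("junction_reads.fa"),
       linear_reads = fp("linear_reads.fa"),
       truth = list(cleavage = planted$truth, circs = pc$truth,
                    junction = jr$truth),
       n_reads = deg$n_reads)
}
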