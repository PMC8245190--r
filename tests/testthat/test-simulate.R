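test_that("genome simulation bookkeeping matches the configuration", {
  cfg0 <- tiny_config(seed = 21, n_cat1 = 0, n_cat2 = 0, n_cat3 = 0,
                      n_a_contigs = 10)
  sim0 <- simulate_genomes(cfg0)
  expect_length(sim0$genome, 10L)
  expect_true(all(sim0$truth$category == "a_chromosome"))
  expect_equal(sim0$germline_plan, sim0$soma_plan)
  expect_true(all(sim0$soma_plan$copies == 2L))

  cfg5 <- tiny_config(seed = 22, n_cat1 = 5, n_cat2 = 0, n_cat3 = 0,
                      n_a_contigs = 10, a_length_range = c(600, 900),
                      min_grc_source_bp = 600)
  expect_warning(sim5 <- simulate_genomes(cfg5), "10% of assembly")
  expect_length(sim5$genome, 15L)
  expect_equal(sum(sim5$truth$category == "high_copy"), 5L)
  tr1 <- sim5$truth[sim5$truth$category == "high_copy", ]
  expect_true(all(tr1$soma_copies == 0L))
  expect_true(all(tr1$germline_copies >= cfg5$cat1_copy_range[1]))
  expect_true(all(tr1$source_a_paralog %in% sim5$truth$contig_id))
})

test_that("identical seeds give byte-identical outputs", {
  cfg <- tiny_config(seed = 33)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- suppressMessages(simulate_dataset(cfg, dir = d1))
  s2 <- suppressMessages(simulate_dataset(cfg, dir = d2))
  for (f in c("assembly.fasta", "germ1.fastq", "soma2.sam", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("substitution mutation has binomial Hamming distance", {
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  expect_identical(mutate_sequence(s, 0, seed = 1), s)
  m1 <- mutate_sequence(s, 1, seed = 2)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(ham(s, m1), 10000L)
  expect_equal(nchar(m1), nchar(s))
  m05 <- mutate_sequence(s, 0.05, seed = 3)
  sd_bin <- sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(ham(s, m05) - 500), 4 * sd_bin)
})

test_that("read simulation respects depth, copy number and error model", {
  cfg <- tiny_config(seed = 44, read_length = 100,
                     depth_per_haploid_copy = 10)
  plan <- data.frame(
    seq_id = c("one", "two"),
    contig_id = c("one", "two"),
    copies = c(1L, 2L),
    sequence = rep(paste(sample(c("A", "C", "G", "T"), 10000,
                                replace = TRUE), collapse = ""), 2),
    stringsAsFactors = FALSE)
  reads <- simulate_reads(plan, cfg, "s", seed = 9)
  n1 <- sum(reads$source_seq_id == "one")
  n2 <- sum(reads$source_seq_id == "two")
  # Poisson around depth * L / read_length = 1,000 (and twice that)
  expect_lt(abs(n1 - 1000), 4 * sqrt(1000))
  expect_lt(abs(n2 - 2000), 4 * sqrt(2000))

  # zero error rate: every read is an exact substring of its source
  # (forward or reverse complement)
  cfg0 <- tiny_config(seed = 44, read_length = 100,
                      depth_per_haploid_copy = 1, error_rate = 0)
  r0 <- simulate_reads(plan[1, ], cfg0, "s", seed = 10)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  hits <- vapply(r0$seq, function(rd)
    grepl(rd, plan$sequence[1], fixed = TRUE) ||
      grepl(rc(rd), plan$sequence[1], fixed = TRUE), logical(1))
  expect_true(all(hits))

  # short template is skipped with a warning
  short <- data.frame(seq_id = "tiny", contig_id = "tiny", copies = 1L,
                      sequence = "ACGTACGT", stringsAsFactors = FALSE)
  expect_warning(simulate_reads(short, cfg, "s", seed = 1),
                 "shorter than read length")
})

test_that("mapper agrees with the exhaustive Hamming scan", {
  set.seed(55)
  g <- genome_index(setNames(
    vapply(c(400, 300, 350), function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), character(1)),
    c("m1", "m2", "m3")))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  draw_read <- function(rate) {
    ci <- sample(3, 1)
    L <- 50
    start <- sample(nchar(g$seqs[ci]) - L + 1, 1)
    rd <- substr(g$seqs[ci], start, start + L - 1)
    rd <- mutate_sequence(rd, rate)
    if (runif(1) < 0.5) rd else rc(rd)
  }
  # error-free reads: every seed is exact, so the seeded search must
  # reproduce the exhaustive scan including tie-breaks
  reads <- vapply(1:120, function(i) draw_read(0), character(1))
  aln <- map_reads(reads, g, k = 15)
  for (i in seq_along(reads)) {
    o <- oracle_best_hit(reads[i], g)
    expect_equal(aln$rname[i], g$ids[o[2]])
    expect_equal(aln$pos[i], o[3])
    expect_equal(unname(aln$nm[i]), o[1])
    expect_equal(bitwAnd(aln$flag[i], 16L) == 16L, o[4] == 1)
  }
  # mutated reads: the reported alignment is never better than the true
  # optimum and its mismatch count is honest at the reported locus
  ham <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))
  mreads <- vapply(1:60, function(i) draw_read(0.04), character(1))
  maln <- map_reads(mreads, g, k = 15)
  for (i in seq_along(mreads)) {
    if (bitwAnd(maln$flag[i], 4L) == 4L) next  # no exact seed survived
    o <- oracle_best_hit(mreads[i], g)
    expect_gte(unname(maln$nm[i]), o[1])
    ref_window <- substr(g$seqs[maln$rname[i]], maln$pos[i],
                         maln$pos[i] + nchar(mreads[i]) - 1)
    expect_equal(unname(maln$nm[i]), ham(maln$seq[i], ref_window))
  }
})

test_that("mapper tie-breaking is deterministic and documented", {
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  g <- genome_index(c(dup1 = s, dup2 = s))
  rd <- substr(s, 20, 79)
  aln <- map_reads(rd, g, k = 31)
  expect_equal(aln$rname, "dup1")   # lowest contig index wins
  expect_equal(aln$pos, 20L)
  expect_equal(aln$flag, 0L)        # forward preferred on a strand tie
})

test_that("error-free reads map back to their true locus", {
  cfg <- tiny_config(seed = 66, error_rate = 0)
  sim <- simulate_genomes(cfg)
  reads <- simulate_reads(sim$soma_plan, cfg, "s", seed = 5)
  aln <- map_reads(reads, sim$genome, k = 31)
  expect_true(all(bitwAnd(aln$flag, 4L) == 0L))
  expect_true(all(aln$nm == 0L))
  expect_equal(aln$rname, reads$source_contig)
})

test_that("collapsed near-identical alleles realise the 3:2 coverage ratio", {
  cfg <- tiny_config(seed = 77, n_a_contigs = 40, n_cat1 = 2, n_cat2 = 1,
                     n_cat3 = 6, a_length_range = c(800, 1200),
                     min_grc_source_bp = 900,
                     depth_per_haploid_copy = 15)
  sim <- simulate_genomes(cfg)
  idx <- kmer_index(sim$genome, 31)
  tally <- function(plan, seed) {
    reads <- simulate_reads(plan, cfg, "x", seed = seed)
    aln <- map_reads(reads, sim$genome, k = 31, index = idx)
    aln <- aln[bitwAnd(aln$flag, 4L) == 0L, ]
    table(factor(aln$rname, levels = sim$genome$ids))
  }
  germ <- tally(sim$germline_plan, 1) + tally(sim$germline_plan, 2)
  soma <- tally(sim$soma_plan, 3) + tally(sim$soma_plan, 4)
  cat3 <- sim$truth$contig_id[sim$truth$category == "low_copy_similar"]
  ratio3 <- sum(germ[cat3]) / sum(soma[cat3])
  expect_gt(ratio3, 1.3)
  expect_lt(ratio3, 1.7)
  cat1 <- sim$truth$contig_id[sim$truth$category == "high_copy"]
  ratio1 <- sum(germ[cat1]) / max(sum(soma[cat1]), 1)
  expect_gt(ratio1, 2)
  # cat3 allele reads really do land on the A paralog (mismapping by
  # paralogy): with zero divergence they are indistinguishable
  cfg0 <- tiny_config(seed = 78, n_cat3 = 2, n_cat1 = 0, n_cat2 = 0,
                      divergence_cat3 = 0, error_rate = 0)
  sim0 <- simulate_genomes(cfg0)
  g3 <- sim0$germline_plan[grepl("^G3", sim0$germline_plan$seq_id), ]
  reads <- simulate_reads(g3, cfg0, "x", seed = 6)
  aln <- map_reads(reads, sim0$genome, k = 31)
  expect_true(all(aln$rname == reads$source_contig))
})

test_that("written SAM files are valid for an independent SAM parser", {
  cfg <- tiny_config(seed = 88)
  sim <- simulate_genomes(cfg)
  reads <- simulate_reads(sim$soma_plan, cfg, "s1", seed = 2)
  aln <- map_reads(reads, sim$genome, k = 21)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, sim$genome, sam)
  sc_file <- suppressMessages(count_sample(sam, sim$genome, "s1", "soma"))
  sc_mem <- suppressMessages(count_sample(aln, sim$genome, "s1", "soma"))
  expect_equal(sc_file$counts, sc_mem$counts)
  expect_equal(sc_file$total_mapped, sc_mem$total_mapped)
})

test_that("observed depth tracks copies x depth_per_haploid_copy", {
  cfg <- tiny_config(seed = 101, n_a_contigs = 12, n_cat1 = 1, n_cat2 = 0,
                     n_cat3 = 0, a_length_range = c(900, 1400),
                     min_grc_source_bp = 1000,
                     depth_per_haploid_copy = 12, cat1_copy_range = c(8, 8))
  sim <- simulate_genomes(cfg)
  reads <- simulate_reads(sim$germline_plan, cfg, "g", seed = 3)
  aln <- map_reads(reads, sim$genome, k = 31)
  sc <- suppressMessages(count_sample(aln, sim$genome, "g", "germline"))
  dep <- mean_depth(sc, sim$genome)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    expected <- tr$germline_copies[i] * cfg$depth_per_haploid_copy
    L <- as.numeric(sim$genome$lengths[tr$contig_id[i]])
    # Poisson bound on total aligned bases / L
    sdev <- sqrt(expected * L / cfg$read_length) * cfg$read_length / L
    expect_lt(abs(dep[tr$contig_id[i]] - expected), 4.5 * sdev)
  }
})
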