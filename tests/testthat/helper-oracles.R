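# Shared fixtures and independent brute-force oracles. Everything here
# is written directly against the definitions (SAM flag bits, per-base
# pileup, the BH step-up, all-position Hamming scans) and never calls
# the package functions it is used to check.

# -- toy genome + SAM fixture -------------------------------------------

toy_genome <- function() {
  genome_index(c(
    c1 = paste(rep("ACGT", 250), collapse = ""),   # 1000 bp
    c2 = paste(rep("GGCA", 125), collapse = "")    # 500 bp
  ))
}

# A hand-written SAM exercising: primary mapped reads, an unmapped read,
# a secondary and a supplementary record, a low-MAPQ read and a deletion
# CIGAR. Single-end throughout.
toy_sam_lines <- function() {
  c("@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:c1\tLN:1000",
    "@SQ\tSN:c2\tLN:500",
    # qname flag rname pos mapq cigar rnext pnext tlen seq qual
    "r1\t0\tc1\t1\t42\t100M\t*\t0\t0\t*\t*",
    "r2\t16\tc1\t51\t42\t100M\t*\t0\t0\t*\t*",
    "r3\t0\tc1\t101\t42\t40M10D40M\t*\t0\t0\t*\t*",
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r5\t0\tc2\t1\t42\t100M\t*\t0\t0\t*\t*",
    "r5\t256\tc1\t201\t0\t100M\t*\t0\t0\t*\t*",   # secondary
    "r6\t2048\tc2\t101\t42\t50M\t*\t0\t0\t*\t*",  # supplementary
    "r7\t0\tc2\t201\t3\t100M\t*\t0\t0\t*\t*")     # low MAPQ
}

write_toy_sam <- function(lines = toy_sam_lines()) {
  path <- tempfile(fileext = ".sam")
  writeLines(lines, path)
  path
}

# Parse raw SAM record lines into a data.frame (no header lines).
parse_sam_records <- function(lines) {
  rec <- lines[!startsWith(lines, "@")]
  f <- strsplit(rec, "\t", fixed = TRUE)
  data.frame(
    qname = vapply(f, `[`, "", 1),
    flag = as.integer(vapply(f, `[`, "", 2)),
    rname = vapply(f, `[`, "", 3),
    pos = as.integer(vapply(f, `[`, "", 4)),
    mapq = as.integer(vapply(f, `[`, "", 5)),
    cigar = vapply(f, `[`, "", 6),
    stringsAsFactors = FALSE)
}

# One-pass tally written directly against the SAM flag definitions:
# count a fragment iff not unmapped (0x4), not secondary (0x100), not
# supplementary (0x800), MAPQ >= min_mapq.
oracle_count <- function(sam_df, contig_ids, min_mapq = 0) {
  counts <- setNames(integer(length(contig_ids)), contig_ids)
  for (i in seq_len(nrow(sam_df))) {
    fl <- sam_df$flag[i]
    if (fl %/% 4 %% 2 == 1) next        # unmapped
    if (fl %/% 256 %% 2 == 1) next      # secondary
    if (fl %/% 2048 %% 2 == 1) next     # supplementary
    if (sam_df$mapq[i] < min_mapq) next
    counts[sam_df$rname[i]] <- counts[sam_df$rname[i]] + 1L
  }
  counts
}

# Explicit per-position pileup from POS + CIGAR (M/=/X add depth, D/N
# consume reference without depth unless include_deletions).
oracle_pileup_depth <- function(sam_df, contig_lengths, min_mapq = 0,
                                include_deletions = FALSE) {
  depth <- lapply(contig_lengths, function(L) numeric(L))
  for (i in seq_len(nrow(sam_df))) {
    fl <- sam_df$flag[i]
    if (fl %/% 4 %% 2 == 1 || fl %/% 256 %% 2 == 1 ||
        fl %/% 2048 %% 2 == 1 || sam_df$mapq[i] < min_mapq) next
    ref <- sam_df$rname[i]
    p <- sam_df$pos[i]
    ops <- regmatches(sam_df$cigar[i],
                      gregexpr("\\d+[MIDNSHP=X]", sam_df$cigar[i]))[[1]]
    for (op in ops) {
      n <- as.integer(sub("[MIDNSHP=X]", "", op))
      o <- sub("\\d+", "", op)
      if (o %in% c("M", "=", "X")) {
        depth[[ref]][p:(p + n - 1)] <- depth[[ref]][p:(p + n - 1)] + 1
        p <- p + n
      } else if (o %in% c("D", "N")) {
        if (o == "D" && include_deletions)
          depth[[ref]][p:(p + n - 1)] <- depth[[ref]][p:(p + n - 1)] + 1
        p <- p + n
      }
      # I/S/H/P consume no reference
    }
  }
  vapply(depth, mean, numeric(1))
}

# -- statistics oracles -------------------------------------------------

# BH step-up exactly as defined: sort ascending, q_(i) =
# min_{j>=i}(p_(j) * n / j) capped at 1, back to input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, ps[i] * n / i)
    q[i] <- min(running, 1)
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Pooled two-sample t-test via t.test(); F should equal t^2 and the
# p-values should agree.
oracle_t2 <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(f = unname(tt$statistic)^2, p = tt$p.value)
}

# All-positions Hamming scan over every contig and both strands;
# returns the best (mm, contig index, pos, strand) under the mapper's
# tie-break order, or NULL if the read is longer than every contig.
oracle_best_hit <- function(read, genome) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  L <- nchar(read)
  best <- NULL
  for (strand in 0:1) {
    q <- if (strand == 0) read else rc(read)
    qv <- utf8ToInt(q)
    for (ci in seq_along(genome$ids)) {
      s <- genome$seqs[ci]
      if (nchar(s) < L) next
      for (start in 1:(nchar(s) - L + 1)) {
        mm <- sum(utf8ToInt(substr(s, start, start + L - 1)) != qv)
        cand <- c(mm, ci, start, strand)
        if (is.null(best) ||
            isTRUE(cand[1] < best[1]) ||
            (cand[1] == best[1] && (cand[2] < best[2] ||
              (cand[2] == best[2] && (cand[3] < best[3] ||
                (cand[3] == best[3] && cand[4] < best[4]))))))
          best <- cand
      }
    }
  }
  best
}

# Build sample_counts objects from a counts matrix (contigs x samples).
counts_from_matrix <- function(mat, groups, genome) {
  lapply(seq_len(ncol(mat)), function(j)
    sample_counts(sprintf("s%d", j), groups[j],
                  setNames(mat[, j], rownames(mat)), genome))
}

# Small, fast simulation config for unit tests.
tiny_config <- function(seed = 11, ...) {
  args <- list(n_a_contigs = 40, a_length_range = c(400, 800),
               n_cat1 = 2, n_cat2 = 1, n_cat3 = 1,
               cat1_copy_range = c(4, 6), min_grc_source_bp = 500,
               read_length = 60, depth_per_haploid_copy = 8,
               error_rate = 0.002, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}
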