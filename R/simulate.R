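# Synthetic germline/soma data generator. Emulates a diploid
# A-chromosome complement shared by both tissues plus germline-only
# sequence in three classes: high-copy collapsed contigs, low-copy
# contigs divergent from their A paralogs, and low-copy alleles nearly
# identical to an A paralog (present in the assembly only as that
# paralog). Read mismapping arises from paralogy, as it does in real
# germline assemblies.

#' Simulation configuration
#'
#' Defaults describe the study conditions the method targets: a diploid
#' background, four germline and four soma replicates, 100 bp single-end
#' reads at 20x per haploid copy, high-copy contigs at 3-10 copies,
#' ~5% divergence for the divergent class and ~0.2% for the similar
#' class.
#'
#' @param n_a_contigs Number of A-chromosome contigs.
#' @param a_length_range A-contig length interval in bp.
#' @param n_cat1,n_cat2,n_cat3 Number of germline-restricted contigs in
#'   each class (high-copy; low-copy divergent; low-copy similar).
#' @param cat1_copy_range Integer interval of germline copy numbers for
#'   the high-copy class.
#' @param divergence_cat2,divergence_cat3 Per-bp substitution rates from
#'   the A paralog for classes 2 and 3.
#' @param min_grc_source_bp Minimum length of A contigs eligible as
#'   paralog sources for classes 1 and 2 (keeps those contigs above the
#'   downstream length threshold).
#' @param read_length Read length in bp (>= 20).
#' @param depth_per_haploid_copy Sequencing depth per haploid copy
#'   (fold-coverage).
#' @param error_rate Per-base sequencing error rate.
#' @param n_germline,n_soma Replicate counts.
#' @param seed Integer seed; everything downstream is reproducible from
#'   it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_a_contigs = 120,
                              a_length_range = c(1500, 3500),
                              n_cat1 = 3, n_cat2 = 2, n_cat3 = 2,
                              cat1_copy_range = c(3, 10),
                              divergence_cat2 = 0.05,
                              divergence_cat3 = 0.002,
                              min_grc_source_bp = 2400,
                              read_length = 100,
                              depth_per_haploid_copy = 20,
                              error_rate = 0.002,
                              n_germline = 4, n_soma = 4,
                              seed = 1L) {
  cfg <- list(n_a_contigs = as.integer(n_a_contigs),
              a_length_range = as.integer(a_length_range),
              n_cat1 = as.integer(n_cat1), n_cat2 = as.integer(n_cat2),
              n_cat3 = as.integer(n_cat3),
              cat1_copy_range = as.integer(cat1_copy_range),
              divergence_cat2 = divergence_cat2,
              divergence_cat3 = divergence_cat3,
              min_grc_source_bp = as.integer(min_grc_source_bp),
              read_length = as.integer(read_length),
              depth_per_haploid_copy = depth_per_haploid_copy,
              error_rate = error_rate,
              n_germline = as.integer(n_germline),
              n_soma = as.integer(n_soma),
              seed = as.integer(seed))
  stopifnot(cfg$n_a_contigs >= 0, cfg$read_length >= 20,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$divergence_cat2 >= 0, cfg$divergence_cat2 <= 1,
            cfg$divergence_cat3 >= 0, cfg$divergence_cat3 <= 1,
            cfg$n_cat1 >= 0, cfg$n_cat2 >= 0, cfg$n_cat3 >= 0,
            length(cfg$a_length_range) == 2,
            cfg$a_length_range[1] >= cfg$read_length,
            cfg$cat1_copy_range[1] >= 1,
            cfg$cat1_copy_range[1] <= cfg$cat1_copy_range[2],
              cfg$depth_per_haploid_copy > 0)
  if (cfg$n_a_contigs == 0 && (cfg$n_cat1 + cfg$n_cat2 + cfg$n_cat3) > 0)
    stop("infeasible config: germline-restricted contigs need A paralogs")
  class(cfg) <- "simulation_config"
  cfg
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Substitution-only sequence mutation
#'
#' Each position is substituted independently with probability `rate` to
#' a uniformly chosen different base; length is preserved. Models
#' paralog divergence without indels.
#'
#' @param sequence Nucleotide string.
#' @param rate Substitution probability per bp, in \[0, 1\].
#' @param seed Optional integer seed; `NULL` uses the current RNG
#'   stream.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(sequence, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(sequence)
  pos <- which(stats::runif(n) < rate)
  if (!length(pos)) return(sequence)
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cur <- match(ch[pos], bases)
  shift <- sample.int(3, length(pos), replace = TRUE)
  ch[pos] <- bases[((cur - 1 + shift) %% 4) + 1]
  paste(ch, collapse = "")
}

#' Simulate assembly, copy plans and ground truth
#'
#' Builds the assembly (A contigs plus class-1 and class-2
#' germline-restricted contigs), the soma copy plan (two copies of every
#' A contig), the germline copy plan (soma plan plus germline-restricted
#' copies, including class-3 extra alleles that are absent from the
#' assembly) and the truth table. Class-1 contigs appear once in the
#' assembly but at elevated copy number in the germline plan, modelling
#' assembly collapse of multicopy sequence.
#'
#' @param cfg A [simulation_config()].
#' @return List with `genome` ([genome_index()]), `germline_plan`,
#'   `soma_plan` (data.frames `seq_id`, `contig_id`, `copies`,
#'   `sequence`) and `truth` (data.frame `contig_id`, `category`,
#'   `germline_copies`, `soma_copies`, `source_a_paralog`).
#' @export
simulate_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n_grc_src <- cfg$n_cat1 + cfg$n_cat2
  a_len <- sample(seq(cfg$a_length_range[1], cfg$a_length_range[2]),
                  cfg$n_a_contigs, replace = TRUE)
  # guarantee enough long A contigs to serve as class-1/2 paralog sources
  if (n_grc_src > 0) {
    long_idx <- which(a_len >= cfg$min_grc_source_bp)
    if (length(long_idx) < n_grc_src) {
      short_idx <- which(a_len < cfg$min_grc_source_bp)
      need <- n_grc_src - length(long_idx)
      if (need > length(short_idx))
        stop("infeasible config: not enough A contigs for paralog sources")
      a_len[short_idx[seq_len(need)]] <-
        cfg$min_grc_source_bp + seq_len(need)
    }
  }
  a_ids <- sprintf("A%04d", seq_len(cfg$n_a_contigs))
  a_seq <- vapply(a_len, random_seq, character(1))
  names(a_seq) <- a_ids

  eligible <- which(a_len >= cfg$min_grc_source_bp)
  n_src <- n_grc_src + cfg$n_cat3
  src_pool <- c(eligible, setdiff(seq_len(cfg$n_a_contigs), eligible))
  if (n_src > cfg$n_a_contigs)
    stop("infeasible config: more germline-restricted contigs than A paralogs")
  src_12 <- if (n_grc_src) sample(eligible, n_grc_src) else integer(0)
  src_3 <- if (cfg$n_cat3)
    sample(setdiff(seq_len(cfg$n_a_contigs), src_12), cfg$n_cat3)
  else integer(0)

  grc_ids <- character(0); grc_seq <- character(0)
  truth <- data.frame(contig_id = a_ids,
                      category = "a_chromosome",
                      germline_copies = 2L, soma_copies = 2L,
                      source_a_paralog = NA_character_,
                      stringsAsFactors = FALSE)
  cat1_copies <- integer(0)
  if (cfg$n_cat1 > 0) {
    ids <- sprintf("G1_%03d", seq_len(cfg$n_cat1))
    src <- src_12[seq_len(cfg$n_cat1)]
    seqs <- vapply(a_seq[src], function(s)
      mutate_sequence(s, cfg$divergence_cat2), character(1))
    cat1_copies <- sample(seq(cfg$cat1_copy_range[1], cfg$cat1_copy_range[2]),
                          cfg$n_cat1, replace = TRUE)
    grc_ids <- c(grc_ids, ids); grc_seq <- c(grc_seq, unname(seqs))
    truth <- rbind(truth, data.frame(
      contig_id = ids, category = "high_copy",
      germline_copies = cat1_copies, soma_copies = 0L,
      source_a_paralog = a_ids[src], stringsAsFactors = FALSE))
  }
  if (cfg$n_cat2 > 0) {
    ids <- sprintf("G2_%03d", seq_len(cfg$n_cat2))
    src <- src_12[cfg$n_cat1 + seq_len(cfg$n_cat2)]
    seqs <- vapply(a_seq[src], function(s)
      mutate_sequence(s, cfg$divergence_cat2), character(1))
    grc_ids <- c(grc_ids, ids); grc_seq <- c(grc_seq, unname(seqs))
    truth <- rbind(truth, data.frame(
      contig_id = ids, category = "low_copy_divergent",
      germline_copies = 1L, soma_copies = 0L,
      source_a_paralog = a_ids[src], stringsAsFactors = FALSE))
  }
  cat3_alleles <- character(0)
  if (cfg$n_cat3 > 0) {
    # extra germline allele nearly identical to its A paralog; NOT an
    # assembly contig — its reads collapse onto the paralog (3:2 ratio)
    seqs <- vapply(a_seq[src_3], function(s)
      mutate_sequence(s, cfg$divergence_cat3), character(1))
    cat3_alleles <- unname(seqs)
    truth$category[src_3] <- "low_copy_similar"
    truth$germline_copies[src_3] <- 3L
  }

  all_seq <- c(a_seq, stats::setNames(grc_seq, grc_ids))
  genome <- genome_index(all_seq)
  grc_assembly_bp <- sum(nchar(grc_seq))
  if (grc_assembly_bp > 0.10 * genome$total_length)
    warning("germline-restricted contigs exceed 10% of assembly length; ",
            "library-size normalisation will noticeably distort expected ",
            "coverage ratios")

  soma_plan <- data.frame(seq_id = a_ids, contig_id = a_ids,
                          copies = 2L, sequence = unname(a_seq),
                          stringsAsFactors = FALSE)
  germ_extra <- data.frame(seq_id = character(0), contig_id = character(0),
                           copies = integer(0), sequence = character(0),
                           stringsAsFactors = FALSE)
  if (cfg$n_cat1 > 0)
    germ_extra <- rbind(germ_extra, data.frame(
      seq_id = sprintf("G1_%03d", seq_len(cfg$n_cat1)),
      contig_id = sprintf("G1_%03d", seq_len(cfg$n_cat1)),
      copies = cat1_copies,
      sequence = grc_seq[seq_len(cfg$n_cat1)], stringsAsFactors = FALSE))
  if (cfg$n_cat2 > 0)
    germ_extra <- rbind(germ_extra, data.frame(
      seq_id = sprintf("G2_%03d", seq_len(cfg$n_cat2)),
      contig_id = sprintf("G2_%03d", seq_len(cfg$n_cat2)),
      copies = 1L,
      sequence = grc_seq[cfg$n_cat1 + seq_len(cfg$n_cat2)],
      stringsAsFactors = FALSE))
  if (cfg$n_cat3 > 0)
    germ_extra <- rbind(germ_extra, data.frame(
      seq_id = sprintf("G3allele_%03d", seq_len(cfg$n_cat3)),
      contig_id = a_ids[src_3],   # where these reads are expected to map
      copies = 1L, sequence = cat3_alleles, stringsAsFactors = FALSE))
  germline_plan <- rbind(soma_plan, germ_extra)

  list(genome = genome, germline_plan = germline_plan,
       soma_plan = soma_plan, truth = truth)
}

# Inject per-base sequencing errors into reads (substitution-only).
inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  inject_errors_cpp(reads, error_rate)
}

#' Simulate single-end reads from a copy plan
#'
#' Read counts per plan entry are Poisson with mean
#' `copies * depth_per_haploid_copy * length / read_length`; start
#' positions are uniform; each read comes from the forward strand or its
#' reverse complement with probability 1/2; per-base errors are injected
#' at `error_rate`. Read names encode the true source sequence for
#' diagnostics.
#'
#' @param plan Copy plan data.frame (see [simulate_genomes()]).
#' @param cfg A [simulation_config()].
#' @param sample_id Sample label (prefixed to read names).
#' @param seed Integer seed for this sample.
#' @return Data.frame `name`, `seq`, `source_seq_id`, `source_contig`.
#' @export
simulate_reads <- function(plan, cfg, sample_id, seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  rl <- cfg$read_length
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    L <- nchar(plan$sequence[i])
    if (L < rl) {
      warning("sequence '", plan$seq_id[i], "' shorter than read length; ",
              "skipped")
      next
    }
    n <- stats::rpois(1, plan$copies[i] * cfg$depth_per_haploid_copy * L / rl)
    if (n == 0) next
    start <- sample.int(L - rl + 1, n, replace = TRUE)
    reads <- substring(plan$sequence[i], start, start + rl - 1)
    rev <- stats::runif(n) < 0.5
    if (any(rev)) reads[rev] <- revcomp_cpp(reads[rev])
    reads <- inject_errors(reads, cfg$error_rate)
    out[[i]] <- data.frame(
      name = sprintf("%s:%s:%d", sample_id, plan$seq_id[i], seq_len(n)),
      seq = reads,
      source_seq_id = plan$seq_id[i],
      source_contig = plan$contig_id[i],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(name = character(0), seq = character(0),
                      source_seq_id = character(0),
                      source_contig = character(0))
  res
}

#' Write reads as FASTQ
#'
#' Fixed quality string (`I`, Q40).
#'
#' @param reads Data.frame from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$name), reads$seq, "+", qual))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Build a k-mer seed index for an assembly
#'
#' Exact k-mer positions over every contig (both strands are handled at
#' query time). Build once and pass to [map_reads()] when mapping
#' several samples against the same assembly.
#'
#' @param genome A [genome_index()].
#' @param k Seed length in bp (1-32; default 31).
#' @return A `kmer_index` handle.
#' @export
kmer_index <- function(genome, k = 31L) {
  stopifnot(inherits(genome, "genome_index"))
  structure(list(ptr = build_index_cpp(unname(genome$seqs), as.integer(k)),
                 k = as.integer(k)),
            class = "kmer_index")
}

#' Map reads to an assembly with the internal best-hit mapper
#'
#' Candidate loci are found by exact k-mer seeding on both strands
#' (non-overlapping seeds plus the final window) and extended to a
#' full-read Hamming comparison; the single best alignment (fewest
#' mismatches; ties broken by lowest contig index, then leftmost
#' position, then forward strand) is reported as a primary record.
#' Reads with no seed hit are reported unmapped.
#'
#' @param reads Data.frame with `name` and `seq` (see
#'   [simulate_reads()]), or a character vector of sequences (names used
#'   as read names).
#' @param genome A [genome_index()].
#' @param k Seed length (default 31, at most the read length).
#' @param index Optional prebuilt [kmer_index()] for `genome` (avoids
#'   re-indexing when mapping many samples).
#' @return Alignment data.frame `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `nm` suitable for [count_sample()] and
#'   [write_sam()].
#' @export
map_reads <- function(reads, genome, k = 31L, index = NULL) {
  stopifnot(inherits(genome, "genome_index"))
  if (is.character(reads))
    reads <- data.frame(name = if (is.null(names(reads)))
      sprintf("read%d", seq_along(reads)) else names(reads),
      seq = unname(reads), stringsAsFactors = FALSE)
  if (nrow(reads) && k > min(nchar(reads$seq)))
    stop("seed length k exceeds read length")
  if (is.null(index)) index <- kmer_index(genome, k)
  stopifnot(inherits(index, "kmer_index"), index$k == k)
  hit <- map_with_index_cpp(index$ptr, reads$seq)
  flag <- ifelse(hit$mapped, ifelse(hit$rev, 16L, 0L), 4L)
  seq_out <- reads$seq
  if (any(hit$mapped & hit$rev))
    seq_out[hit$mapped & hit$rev] <- revcomp_cpp(reads$seq[hit$mapped & hit$rev])
  ref_idx <- ifelse(hit$mapped, hit$ref, NA_integer_)
  rname <- genome$ids[ref_idx]
  rname[is.na(rname)] <- "*"
  data.frame(
    qname = reads$name,
    flag = flag,
    rname = rname,
    pos = ifelse(hit$mapped, hit$pos, 0L),
    mapq = ifelse(hit$mapped, 42L, 0L),
    cigar = ifelse(hit$mapped, paste0(nchar(reads$seq), "M"), "*"),
    seq = seq_out,
    nm = ifelse(hit$mapped, hit$mismatches, NA_integer_),
    stringsAsFactors = FALSE)
}

#' Write alignments as SAM
#'
#' Emits a valid single-end SAM file (header with one `@SQ` line per
#' contig; primary records only; fixed quality).
#'
#' @param aln Alignment data.frame from [map_reads()].
#' @param genome A [genome_index()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$ids,
                      as.integer(genome$lengths)))
  qual <- strrep("I", nchar(aln$seq))
  nm <- ifelse(is.na(aln$nm), "", sprintf("\tNM:i:%d", aln$nm))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                 aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                 aln$cigar, aln$seq, qual, nm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rec), con)
  invisible(path)
}

#' Simulate a complete germline/soma dataset
#'
#' Runs [simulate_genomes()], draws reads for every replicate, maps them
#' with the internal mapper and counts fragments per contig. When `dir`
#' is given, also writes the assembly FASTA, per-sample FASTQ and SAM,
#' truth and design TSVs, and a run-manifest JSON echoing the full
#' configuration.
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional output directory (created if absent).
#' @param k Mapper seed length.
#' @return List with `genome`, `truth`, `design` (sample_id, group,
#'   path), `counts` (list of `sample_counts`), `alignments` (list of
#'   alignment data.frames) and `paths` (when `dir` given).
#' @export
simulate_dataset <- function(cfg, dir = NULL, k = 31L) {
  stopifnot(inherits(cfg, "simulation_config"))
  sim <- simulate_genomes(cfg)
  samples <- data.frame(
    sample_id = c(sprintf("germ%d", seq_len(cfg$n_germline)),
                  sprintf("soma%d", seq_len(cfg$n_soma))),
    group = c(rep("germline", cfg$n_germline),
              rep("soma", cfg$n_soma)),
    stringsAsFactors = FALSE)
  write_files <- !is.null(dir)
  if (write_files && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  if (write_files) {
    paths$assembly <- file.path(dir, "assembly.fasta")
    write_fasta(sim$genome, paths$assembly)
  }
  counts <- vector("list", nrow(samples))
  alignments <- vector("list", nrow(samples))
  sam_paths <- character(nrow(samples))
  idx <- kmer_index(sim$genome, k)
  for (i in seq_len(nrow(samples))) {
    plan <- if (samples$group[i] == "germline") sim$germline_plan
            else sim$soma_plan
    reads <- simulate_reads(plan, cfg, samples$sample_id[i],
                            seed = cfg$seed + 1009L * i)
    aln <- map_reads(reads, sim$genome, k = k, index = idx)
    alignments[[i]] <- aln
    counts[[i]] <- count_sample(aln, sim$genome, samples$sample_id[i],
                                samples$group[i])
    if (write_files) {
      fq <- file.path(dir, paste0(samples$sample_id[i], ".fastq"))
      write_fastq(reads, fq)
      sam_paths[i] <- file.path(dir, paste0(samples$sample_id[i], ".sam"))
      write_sam(aln, sim$genome, sam_paths[i])
    }
  }
  names(counts) <- samples$sample_id
  names(alignments) <- samples$sample_id
  design <- cbind(samples, path = sam_paths, stringsAsFactors = FALSE)
  if (write_files) {
    paths$truth <- file.path(dir, "truth.tsv")
    utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$design <- file.path(dir, "design.tsv")
    utils::write.table(design, paths$design, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(
      list(config = unclass(cfg), paths = paths,
           samples = samples$sample_id),
      paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  list(genome = sim$genome, truth = sim$truth, design = design,
       counts = counts, alignments = alignments, paths = paths)
}
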