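# Per-sample fragment counting from single-end alignments.

#' Count primary alignments per contig for one sample
#'
#' Counts one fragment per read whose record is mapped, primary (neither
#' secondary nor supplementary) and has mapping quality at or above
#' `min_mapq`. Fragments equal reads: the single-end contract mirrors a
#' best-hit aligner reporting one alignment per read. Paired-end flags are
#' a hard error. Aligned reference length per counted read is accumulated
#' from the CIGAR (`M`/`=`/`X`; deletions optionally included).
#'
#' @param alignments Path to a SAM or BAM file, or an in-memory alignment
#'   data.frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar` (as produced by [map_reads()]).
#' @param genome A [genome_index()]; alignment reference names must be a
#'   subset of its contig ids.
#' @param sample_id Sample label.
#' @param group `"germline"` or `"soma"`.
#' @param min_mapq Minimum mapping quality (default 0: no filter, matching
#'   a best-hit aligner run with default parameters).
#' @param include_deletions Count deletions (`D`) as aligned reference
#'   bases (default `FALSE`).
#' @return A `sample_counts` object: list with `sample_id`, `group`,
#'   `counts` (named integer per contig), `aligned_bases` (named numeric),
#'   `total_mapped`, `n_unmapped`.
#' @export
count_sample <- function(alignments, genome, sample_id, group,
                         min_mapq = 0L, include_deletions = FALSE) {
  stopifnot(inherits(genome, "genome_index"))
  group <- match.arg(group, c("germline", "soma"))
  if (is.character(alignments) && length(alignments) == 1) {
    aln <- read_alignments(alignments)
  } else if (is.data.frame(alignments)) {
    aln <- alignments
  } else {
    stop("'alignments' must be a SAM/BAM path or an alignment data.frame")
  }
  need <- c("qname", "flag", "rname", "mapq", "cigar")
  stopifnot(all(need %in% names(aln)))

  flag <- as.integer(aln$flag)
  if (any(bitwAnd(flag, 0x1L) != 0L))
    stop("paired-end flags present; this pipeline is single-end only ",
         "(map just the forward reads)")
  mapped <- bitwAnd(flag, 0x4L) == 0L
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  keep <- mapped & primary & !is.na(aln$mapq) & aln$mapq >= min_mapq
  n_unmapped <- sum(!mapped)

  rname <- as.character(aln$rname[keep])
  unknown <- setdiff(unique(rname), genome$ids)
  if (length(unknown))
    stop("alignment reference name not in genome: ", unknown[1])

  cig <- aln$cigar[keep]
  # reference span (M/=/X/D/N), then drop ops not counted as aligned
  ref_len <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  drop_ops <- c("N", if (!include_deletions) "D")
  has_drop <- grepl(paste(drop_ops, collapse = "|"), cig)
  if (any(has_drop)) {
    dropped <- vapply(
      GenomicAlignments::explodeCigarOpLengths(cig[has_drop],
                                               ops = drop_ops),
      sum, numeric(1))
    ref_len[has_drop] <- ref_len[has_drop] - dropped
  }

  counts <- integer(length(genome$ids))
  names(counts) <- genome$ids
  ab <- numeric(length(genome$ids))
  names(ab) <- genome$ids
  if (length(rname)) {
    f <- factor(rname, levels = genome$ids)
    counts[] <- tabulate(f, nbins = length(genome$ids))
    sums <- rowsum(ref_len, f)
    ab[rownames(sums)] <- as.numeric(sums)
  }
  message(sprintf("[%s] %d reads counted, %d unmapped ignored",
                  sample_id, sum(counts), n_unmapped))
  structure(
    list(sample_id = sample_id, group = group, counts = counts,
         aligned_bases = ab, total_mapped = sum(counts),
         n_unmapped = n_unmapped),
    class = "sample_counts"
  )
}

#' Construct a sample_counts object from a count vector
#'
#' For counts imported from elsewhere (or built in code): validates
#' against the genome and fills `aligned_bases` if not given.
#'
#' @param sample_id Sample label.
#' @param group `"germline"` or `"soma"`.
#' @param counts Named non-negative integer vector, one entry per
#'   genome contig (missing contigs are taken as zero).
#' @param genome A [genome_index()].
#' @param aligned_bases Optional named numeric vector; defaults to
#'   `counts` (one aligned base per fragment, a lower bound).
#' @return A `sample_counts` object (see [count_sample()]).
#' @export
sample_counts <- function(sample_id, group, counts, genome,
                          aligned_bases = NULL) {
  stopifnot(inherits(genome, "genome_index"))
  group <- match.arg(group, c("germline", "soma"))
  unknown <- setdiff(names(counts), genome$ids)
  if (length(unknown)) stop("unknown contig id: ", unknown[1])
  full <- stats::setNames(integer(length(genome$ids)), genome$ids)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("counts must be non-negative")
  if (is.null(aligned_bases)) {
    ab <- as.numeric(full)
  } else {
    ab <- stats::setNames(numeric(length(genome$ids)), genome$ids)
    ab[names(aligned_bases)] <- as.numeric(aligned_bases)
  }
  names(ab) <- genome$ids
  structure(
    list(sample_id = sample_id, group = group, counts = full,
         aligned_bases = ab, total_mapped = sum(full), n_unmapped = 0L),
    class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("sample_counts '%s' (%s): %d mapped fragments over %d contigs\n",
              x$sample_id, x$group, x$total_mapped, length(x$counts)))
  invisible(x)
}

# Read SAM/BAM alignment fields via Rsamtools. SAM input is converted to a
# temporary BAM first.
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(
    qname = res$qname,
    flag = as.integer(res$flag),
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    stringsAsFactors = FALSE
  )
}

#' Mean per-base depth per contig
#'
#' Depth is aligned reference bases divided by contig length
#' (fold-coverage). Feeds copy-number estimation.
#'
#' @param sc A `sample_counts` object.
#' @param genome A [genome_index()].
#' @return Named numeric vector of mean depths, one per contig.
#' @export
mean_depth <- function(sc, genome) {
  stopifnot(inherits(sc, "sample_counts"), inherits(genome, "genome_index"))
  if (!all(names(sc$aligned_bases) == genome$ids))
    stop("sample_counts and genome contigs are inconsistent")
  sc$aligned_bases / as.numeric(genome$lengths)
}

#' Write per-sample counts as TSV
#'
#' Columns: `contig_id`, `count`, `aligned_bases`, `mean_depth`.
#'
#' @inheritParams mean_depth
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(sc, genome, path) {
  d <- data.frame(
    contig_id = names(sc$counts),
    count = as.integer(sc$counts),
    aligned_bases = as.numeric(sc$aligned_bases),
    mean_depth = as.numeric(mean_depth(sc, genome)),
    stringsAsFactors = FALSE
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Tab-separated file with header columns `sample_id`, `group`, `path`.
#' Group must be `germline` or `soma`.
#'
#' @param path Design TSV path.
#' @return Data.frame with those three columns.
#' @export
read_design <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "path")
  if (!all(need %in% names(d)))
    stop("design file must have columns: ", paste(need, collapse = ", "))
  if (!all(d$group %in% c("germline", "soma")))
    stop("design groups must be 'germline' or 'soma'")
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in design")
  d[, need]
}
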