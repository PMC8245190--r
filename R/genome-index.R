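# Assembly handling: contig registry and the contig-as-single-transcript
# annotation that defines the quantification units.

#' Construct a genome index from sequences
#'
#' A `genome_index` is the registry of contigs being interrogated: the
#' universe of testable units. Contig order is preserved from the input.
#'
#' @param sequences Named character vector of nucleotide sequences
#'   (upper-case `A`/`C`/`G`/`T`/`N`); names are contig ids.
#' @return An object of class `genome_index` with elements `ids`, `seqs`
#'   (named character), `lengths` (named integer) and `total_length`.
#' @export
genome_index <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop("every sequence must have a non-empty contig id")
  if (any(grepl("\\s", ids)))
    stop("contig ids must not contain whitespace: ",
         ids[grepl("\\s", ids)][1])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate contig id: ", dup[1])
  sequences <- toupper(unname(as.character(sequences)))
  bad <- regexpr("[^ACGTN]", sequences)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("contig '%s' has a non-IUPAC (non-ACGTN) character at position %d",
                 ids[i], bad[i]))
  }
  if (any(nchar(sequences) < 1))
    stop("contig '", ids[which(nchar(sequences) < 1)[1]], "' is empty")
  lens <- nchar(sequences)
  names(sequences) <- ids
  names(lens) <- ids
  structure(
    list(ids = ids, seqs = sequences, lengths = lens,
         total_length = sum(lens)),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d contigs, %s bp total\n",
              length(x$ids), format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' @export
length.genome_index <- function(x) length(x$ids)

#' Read a genome assembly from FASTA
#'
#' The header token before the first whitespace becomes the contig id;
#' sequences are upper-cased. Duplicate ids, an empty file, or characters
#' outside `A`/`C`/`G`/`T`/`N` are hard errors.
#'
#' @param path Path to a FASTA file (plain or line-wrapped).
#' @return A [genome_index()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(dss))
  seqs <- as.character(dss)
  names(seqs) <- ids
  genome_index(seqs)
}

#' Write a genome index to FASTA
#'
#' @param genome A [genome_index()].
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_index"))
  dss <- Biostrings::DNAStringSet(genome$seqs)
  names(dss) <- genome$ids
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Build the contig-as-single-transcript annotation
#'
#' Every contig is demarcated as one transcript spanning its full length on
#' the `+` strand, with `gene_id` and `transcript_id` equal to the contig
#' id. This defines the quantification units for FPKM.
#'
#' @param genome A [genome_index()].
#' @return A data.frame with columns `contig_id`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id`; one row per contig, coordinates 1-based
#'   inclusive.
#' @export
build_contig_annotation <- function(genome) {
  stopifnot(inherits(genome, "genome_index"))
  if (length(genome$ids) == 0) stop("genome has no contigs")
  data.frame(
    contig_id = genome$ids,
    start = 1L,
    end = unname(genome$lengths),
    strand = "+",
    transcript_id = genome$ids,
    gene_id = genome$ids,
    stringsAsFactors = FALSE
  )
}

#' Write contig annotations as GFF3
#'
#' Emits, per contig, a `transcript` line and a single `exon` line spanning
#' the full contig (9 tab-separated columns, 1-based inclusive coordinates,
#' deterministic input order). Attributes carry `gene_id` and
#' `transcript_id`.
#'
#' @param annotations Data.frame as returned by [build_contig_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path) {
  stopifnot(is.data.frame(annotations),
            all(c("contig_id", "start", "end", "strand",
                  "transcript_id", "gene_id") %in% names(annotations)))
  tline <- sprintf(
    "%s\tgrcoverage\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s.t1;gene_id=%s;transcript_id=%s",
    annotations$contig_id, annotations$start, annotations$end,
    annotations$strand, annotations$transcript_id, annotations$gene_id,
    annotations$transcript_id)
  eline <- sprintf(
    "%s\tgrcoverage\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon1;Parent=%s.t1;gene_id=%s;transcript_id=%s",
    annotations$contig_id, annotations$start, annotations$end,
    annotations$strand, annotations$transcript_id,
    annotations$transcript_id, annotations$gene_id,
    annotations$transcript_id)
  lines <- c("##gff-version 3", as.vector(rbind(tline, eline)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read contig annotations back from GFF3
#'
#' Inverse of [write_gff3()]: parses the `transcript` lines of a 9-column
#' GFF3 file into the annotation data.frame.
#'
#' @param path GFF3 path.
#' @return Annotation data.frame (see [build_contig_annotation()]).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9))
    stop("malformed GFF3: expected 9 tab-separated columns")
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "transcript"
  m <- m[keep, , drop = FALSE]
  attr_get <- function(attrs, key) {
    v <- sub(sprintf(".*(?:^|;)%s=([^;]*).*", key), "\\1", attrs)
    v
  }
  data.frame(
    contig_id = m[, 1],
    start = as.integer(m[, 4]),
    end = as.integer(m[, 5]),
    strand = m[, 7],
    transcript_id = attr_get(m[, 9], "transcript_id"),
    gene_id = attr_get(m[, 9], "gene_id"),
    stringsAsFactors = FALSE
  )
}
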