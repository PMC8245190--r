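# End-to-end orchestration: counts -> differential table -> calls ->
# size estimate -> reports.

#' Analyse a set of per-sample counts
#'
#' Core in-memory pipeline: differential coverage, high-confidence
#' calls, copy-number estimation from germline depth, categories and the
#' copy-number-compensated total length of called contigs.
#'
#' @param counts_list List of `sample_counts` (both groups).
#' @param genome A [genome_index()].
#' @param thresholds A [threshold_set()].
#' @param epsilon Fold-change pseudocount (FPKM).
#' @param soma_fpkm_floor,similar_band Passed to [categorize()].
#' @param ploidy Background ploidy for [baseline_depth()].
#' @return List with `differential` (all contigs), `calls` (tested
#'   contigs: id, is_hcgrc, category, est_copy_number, adjusted_bp),
#'   `baseline_depth`, `size` (see [estimate_total_grc_length()], NULL
#'   when nothing is called) and `summary` (named list).
#' @export
analyze_counts <- function(counts_list, genome,
                           thresholds = threshold_set(),
                           epsilon = 0.01,
                           soma_fpkm_floor = 1.0,
                           similar_band = c(1.2, 2.0),
                           ploidy = 2) {
  groups <- vapply(counts_list, `[[`, character(1), "group")
  if (sum(groups == "germline") < 3 || sum(groups == "soma") < 3)
    warning("fewer than 3 replicates in a group; at least three ",
            "replicate animals are recommended for stable q-values")
  diff <- run_differential(counts_list, genome, epsilon = epsilon)

  germ_depths <- lapply(counts_list[groups == "germline"],
                        mean_depth, genome = genome)
  base <- baseline_depth(germ_depths, genome, ploidy = ploidy)
  mean_germ_depth <- Reduce(`+`, germ_depths) / length(germ_depths)
  cn_all <- estimate_copy_number(mean_germ_depth, base)

  tested <- diff[diff$tested, , drop = FALSE]
  calls <- categorize(tested, cn_all[tested$contig_id],
                      thresholds = thresholds,
                      soma_fpkm_floor = soma_fpkm_floor,
                      similar_band = similar_band)
  calls$adjusted_bp <- 0
  size <- NULL
  if (any(calls$is_hcgrc)) {
    hc <- calls[calls$is_hcgrc, ]
    size <- estimate_total_grc_length(
      hc$contig_id, hc$est_copy_number,
      genome$lengths[hc$contig_id])
    calls$adjusted_bp[calls$is_hcgrc] <-
      unname(size$per_contig_adjusted_bp[hc$contig_id])
  }
  lib_sizes <- vapply(counts_list, `[[`, numeric(1), "total_mapped")
  names(lib_sizes) <- vapply(counts_list, `[[`, character(1), "sample_id")
  summary <- list(
    n_germline = sum(groups == "germline"),
    n_soma = sum(groups == "soma"),
    library_sizes = as.list(lib_sizes),
    n_contigs = length(genome$ids),
    n_tested = nrow(tested),
    n_hcgrc = sum(calls$is_hcgrc),
    category_counts = as.list(table(calls$category)),
    baseline_depth = base,
    total_adjusted_bp = if (is.null(size)) 0 else size$total_adjusted_bp,
    thresholds = unclass(thresholds)
  )
  list(differential = diff, calls = calls, baseline_depth = base,
       size = size, summary = summary)
}

#' Run the full pipeline from files
#'
#' Reads the assembly and the sample design (`sample_id`, `group`,
#' `path` to SAM/BAM), counts primary alignments per contig per sample,
#' runs the differential analysis and calling, and writes the
#' differential table, volcano table, calls table and a summary JSON
#' into `out_dir`. Outputs are deterministic given the inputs; rows
#' follow assembly contig order.
#'
#' @param assembly Path to the assembly FASTA.
#' @param design Path to the design TSV, or an equivalent data.frame.
#' @param out_dir Output directory (created if absent); `NULL` skips
#'   writing.
#' @param thresholds A [threshold_set()].
#' @param epsilon Fold-change pseudocount (FPKM).
#' @param min_mapq Minimum mapping quality for counting.
#' @param ... Passed to [analyze_counts()].
#' @return The [analyze_counts()] result, with `genome`, `counts` and
#'   (when written) `paths` attached, invisibly.
#' @export
run_pipeline <- function(assembly, design, out_dir = NULL,
                         thresholds = threshold_set(), epsilon = 0.01,
                         min_mapq = 0L, ...) {
  genome <- read_fasta(assembly)
  if (is.character(design)) design <- read_design(design)
  counts_list <- lapply(seq_len(nrow(design)), function(i)
    count_sample(design$path[i], genome, design$sample_id[i],
                 design$group[i], min_mapq = min_mapq))
  res <- analyze_counts(counts_list, genome, thresholds = thresholds,
                        epsilon = epsilon, ...)
  res$genome <- genome
  res$counts <- counts_list
  message(sprintf(
    "pipeline: %d samples, %d/%d contigs tested, %d called high-confidence",
    nrow(design), res$summary$n_tested, res$summary$n_contigs,
    res$summary$n_hcgrc))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(
      differential = file.path(out_dir, "differential.tsv"),
      volcano = file.path(out_dir, "volcano.tsv"),
      calls = file.path(out_dir, "calls.tsv"),
      summary = file.path(out_dir, "summary.json"))
    write_differential_tsv(res$differential, paths$differential)
    utils::write.table(volcano_table(res$differential), paths$volcano,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$calls, paths$calls, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(res$summary, paths$summary, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    res$paths <- paths
  }
  invisible(res)
}
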