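# Per-contig FPKM, germline-vs-soma fold change, two-group F-test and
# BH-FDR correction: the native quantification + differential test.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count * 1e9 / (length_bp * total_mapped)`. Applied here to DNA
#' coverage of contigs (one contig = one intronless transcript), FPKM
#' normalises for both contig length and sequencing library depth.
#'
#' @param count Non-negative fragment count (vectorised).
#' @param length_bp Contig length in bp (>= 1).
#' @param total_mapped Total mapped fragments in the library (>= 1).
#' @return FPKM value(s).
#' @export
fpkm <- function(count, length_bp, total_mapped) {
  if (any(total_mapped == 0)) stop("empty library: total_mapped is 0")
  stopifnot(all(length_bp >= 1), all(count >= 0))
  count * 1e9 / (as.numeric(length_bp) * as.numeric(total_mapped))
}

#' Build the contig-by-sample FPKM matrix
#'
#' @param counts_list List of `sample_counts` objects (see
#'   [count_sample()]), one per sample.
#' @param genome A [genome_index()].
#' @return An `fpkm_table`: list with `values` (contig x sample matrix),
#'   `lengths` (named bp), `design` (named character sample -> group),
#'   `total_mapped` (named integer).
#' @export
fpkm_table <- function(counts_list, genome) {
  stopifnot(length(counts_list) >= 1,
            all(vapply(counts_list, inherits, logical(1), "sample_counts")))
  ids <- vapply(counts_list, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id among counts")
  vals <- vapply(counts_list, function(sc) {
    if (!all(names(sc$counts) == genome$ids))
      stop("sample '", sc$sample_id, "' counts inconsistent with genome")
    fpkm(sc$counts, genome$lengths, sc$total_mapped)
  }, numeric(length(genome$ids)))
  vals <- matrix(vals, nrow = length(genome$ids),
                 dimnames = list(genome$ids, ids))
  design <- vapply(counts_list, `[[`, character(1), "group")
  names(design) <- ids
  tm <- vapply(counts_list, `[[`, numeric(1), "total_mapped")
  names(tm) <- ids
  structure(list(values = vals, lengths = genome$lengths,
                 design = design, total_mapped = tm),
            class = "fpkm_table")
}

#' @export
print.fpkm_table <- function(x, ...) {
  cat(sprintf("fpkm_table: %d contigs x %d samples (%d germline, %d soma)\n",
              nrow(x$values), ncol(x$values),
              sum(x$design == "germline"), sum(x$design == "soma")))
  invisible(x)
}

#' Germline-to-soma fold change
#'
#' Linear-scale ratio of group mean FPKM with a pseudocount guard:
#' `(mean_germline + epsilon) / (mean_soma + epsilon)`. Taking this ratio
#' normalises for read mismapping between paralogs and for copy-number
#' variation shared by both tissues.
#'
#' @param fpkm_germline,fpkm_soma Per-replicate FPKM values (>= 1 each).
#' @param epsilon Pseudocount in FPKM units (default 0.01).
#' @return List with `fold_change` and `log2_fc`.
#' @export
fold_change <- function(fpkm_germline, fpkm_soma, epsilon = 0.01) {
  stopifnot(length(fpkm_germline) >= 1, length(fpkm_soma) >= 1,
            epsilon >= 0)
  fc <- (mean(fpkm_germline) + epsilon) / (mean(fpkm_soma) + epsilon)
  list(fold_change = fc, log2_fc = log2(fc))
}

# Vectorised two-group F-test over matrix rows. y: contigs x samples of
# transformed coverages; g: logical, TRUE = germline. Returns data.frame
# f_stat, p_value. Rows with total sum of squares below tol get F = 0,
# p = 1 (no variance, nothing to test).
row_f_test <- function(y, g, tol = 1e-12) {
  n1 <- sum(g); n2 <- sum(!g); n <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("insufficient replicates: need >= 2 per group")
  m1 <- rowMeans(y[, g, drop = FALSE])
  m2 <- rowMeans(y[, !g, drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((y[, g, drop = FALSE] - m1)^2) +
    rowSums((y[, !g, drop = FALSE] - m2)^2)
  sst <- ssb + ssw
  f <- ifelse(sst < tol, 0, ssb / (ssw / (n - 2)))
  p <- ifelse(sst < tol, 1, stats::pf(f, 1, n - 2, lower.tail = FALSE))
  data.frame(f_stat = f, p_value = p)
}

#' Two-group F-test on transformed coverages of one contig
#'
#' Ordinary-least-squares F-test of the group model against the
#' intercept-only model (df1 = 1, df2 = n - 2); equivalent to the squared
#' pooled-variance t statistic. Values are conventionally
#' `log2(FPKM + 1)`. If all values are equal (total sum of squares below
#' tolerance) returns `f_stat = 0`, `p_value = 1`.
#'
#' @param values Numeric vector, one value per sample.
#' @param groups Character/factor of the same length with exactly two
#'   levels, each with >= 2 replicates.
#' @return List with `f_stat` and `p_value`.
#' @export
group_f_test <- function(values, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  r <- row_f_test(matrix(values, nrow = 1), groups == lev[1])
  list(f_stat = r$f_stat, p_value = r$p_value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: sort p ascending, take the running minimum of
#' `p * n / rank` from the top rank down, cap at 1, map back to input
#' order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full differential coverage analysis
#'
#' One record per contig: per-sample FPKM, linear fold change (germline /
#' soma, pseudocount `epsilon`), F-test on `log2(FPKM + 1)` and BH
#' q-values over all tested contigs as a single family. Contigs with zero
#' counts in every sample are flagged untested (`tested = FALSE`, fold
#' change 1, NA statistics); they carry no signal.
#'
#' @param counts_list List of `sample_counts`, >= 2 per group for the test
#'   path.
#' @param genome A [genome_index()].
#' @param epsilon Fold-change pseudocount in FPKM units (default 0.01).
#' @return A data.frame with one row per contig: `contig_id`, `length_bp`,
#'   `mean_fpkm_germline`, `mean_fpkm_soma`, `fold_change`, `log2_fc`,
#'   `f_stat`, `p_value`, `q_value`, `tested`. The FPKM table is attached
#'   as attribute `"fpkm"`.
#' @export
run_differential <- function(counts_list, genome, epsilon = 0.01) {
  ft <- fpkm_table(counts_list, genome)
  g <- ft$design == "germline"
  if (sum(g) < 2 || sum(!g) < 2)
    stop("insufficient replicates: need >= 2 germline and >= 2 soma samples")
  v <- ft$values
  mg <- rowMeans(v[, g, drop = FALSE])
  ms <- rowMeans(v[, !g, drop = FALSE])
  fc <- (mg + epsilon) / (ms + epsilon)
  tested <- rowSums(v) > 0
  out <- data.frame(
    contig_id = rownames(v),
    length_bp = as.integer(ft$lengths[rownames(v)]),
    mean_fpkm_germline = mg,
    mean_fpkm_soma = ms,
    fold_change = fc,
    log2_fc = log2(fc),
    f_stat = NA_real_,
    p_value = NA_real_,
    q_value = NA_real_,
    tested = tested,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (any(tested)) {
    ft_res <- row_f_test(log2(v[tested, , drop = FALSE] + 1), g)
    out$f_stat[tested] <- ft_res$f_stat
    out$p_value[tested] <- ft_res$p_value
    out$q_value[tested] <- bh_fdr(ft_res$p_value)
  }
  attr(out, "fpkm") <- ft
  out
}

#' Write the differential table as TSV
#'
#' Per-sample FPKM columns followed by the summary statistics.
#'
#' @param diff Result of [run_differential()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_tsv <- function(diff, path) {
  ft <- attr(diff, "fpkm")
  d <- diff
  if (!is.null(ft)) {
    fp <- as.data.frame(ft$values)
    names(fp) <- paste0("fpkm_", colnames(ft$values))
    d <- cbind(diff[, c("contig_id", "length_bp")], fp,
               diff[, setdiff(names(diff), c("contig_id", "length_bp"))])
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Volcano table: effect size vs significance
#'
#' @param diff Result of [run_differential()].
#' @return Data.frame `contig_id`, `log2_fc`, `minus_log10_q` (untested
#'   contigs dropped).
#' @export
volcano_table <- function(diff) {
  d <- diff[diff$tested, c("contig_id", "log2_fc", "q_value")]
  data.frame(contig_id = d$contig_id, log2_fc = d$log2_fc,
             minus_log10_q = -log10(pmax(d$q_value, .Machine$double.xmin)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Volcano plot of differential coverage
#'
#' Fold change against significance with the classification thresholds
#' drawn as reference lines.
#'
#' @param diff Result of [run_differential()].
#' @param thresholds A [threshold_set()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff, thresholds = threshold_set()) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  v <- volcano_table(diff)
  ggplot2::ggplot(v, ggplot2::aes(x = log2_fc, y = minus_log10_q)) +
    ggplot2::geom_point(alpha = 0.25) +
    ggplot2::geom_vline(xintercept = log2(thresholds$min_fold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(thresholds$max_q),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 FPKM fold change (germline / soma)",
                  y = "-log10 q-value")
}
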