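# Calling high-confidence germline-restricted contigs, category
# assignment and copy-number-compensated total length estimation.

#' Threshold set for high-confidence calls
#'
#' Defaults follow the published operating point: 2-fold
#' germline-to-soma enrichment (inclusive), q-value below 0.05 (strict)
#' and contig length above 2,000 bp (strict).
#'
#' @param min_fold Minimum linear fold change (inclusive, > 0).
#' @param max_q Maximum q-value (exclusive, in (0, 1]).
#' @param min_length_bp Minimum contig length in bp (exclusive, >= 0).
#' @return A `threshold_set` list.
#' @export
threshold_set <- function(min_fold = 2.0, max_q = 0.05,
                          min_length_bp = 2000L) {
  stopifnot(min_fold > 0, max_q > 0, max_q <= 1, min_length_bp >= 0)
  structure(list(min_fold = min_fold, max_q = max_q,
                 min_length_bp = as.integer(min_length_bp)),
            class = "threshold_set")
}

#' Call high-confidence germline-restricted contigs
#'
#' A contig is called when `fold_change >= min_fold` AND
#' `q_value < max_q` AND `length_bp > min_length_bp`. Untested records
#' (no q-value) are an error: filter on `tested` first.
#'
#' @param diff Differential data.frame (see [run_differential()]) or any
#'   data.frame with `fold_change`, `q_value`, `length_bp`.
#' @param thresholds A [threshold_set()].
#' @return Logical vector, one element per row of `diff`.
#' @export
classify_hcgrc <- function(diff, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"),
            all(c("fold_change", "q_value", "length_bp") %in% names(diff)))
  if (any(is.na(diff$q_value)))
    stop("untested records present (q_value is NA); ",
         "filter to tested contigs before classification")
  diff$fold_change >= thresholds$min_fold &
    diff$q_value < thresholds$max_q &
    diff$length_bp > thresholds$min_length_bp
}

# Weighted median: smallest x whose cumulative weight reaches half the
# total. Used for the depth baseline (weights = contig lengths).
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' Estimate the single-copy depth baseline from germline samples
#'
#' Length-weighted median of per-contig mean germline depth across all
#' contigs, averaged over replicates, divided by `ploidy`. The median is
#' dominated by the diploid A-chromosome background, so dividing by the
#' ploidy (default 2) yields the sequencing depth of one haploid copy —
#' the unit in which copy numbers are reported.
#'
#' @param depths List of per-replicate depth vectors (named per contig,
#'   see [mean_depth()]); germline samples only.
#' @param genome A [genome_index()].
#' @param ploidy Copies per contig of the background complement
#'   (default 2, diploid).
#' @return Baseline depth of a single haploid copy (fold-coverage).
#' @export
baseline_depth <- function(depths, genome, ploidy = 2) {
  if (!is.list(depths)) depths <- list(depths)
  stopifnot(length(depths) >= 1, inherits(genome, "genome_index"))
  per_rep <- vapply(depths, function(d) {
    d <- d[genome$ids]
    if (any(is.na(d))) stop("depth vector missing contigs")
    weighted_median(as.numeric(d), as.numeric(genome$lengths))
  }, numeric(1))
  b <- mean(per_rep) / ploidy
  if (b <= 0) stop("all-zero germline depths: cannot set a baseline")
  b
}

#' Copy number from germline depth
#'
#' @param depth Per-contig mean germline depth (fold-coverage).
#' @param baseline Single-copy baseline depth (see [baseline_depth()]).
#' @return `depth / baseline`, unrounded.
#' @export
estimate_copy_number <- function(depth, baseline) {
  stopifnot(baseline > 0)
  depth / baseline
}

#' Copy-number-compensated total length of called contigs
#'
#' Each called contig contributes `length_bp * max(1, copy_number)`: a
#' collapsed multicopy contig counts once per estimated copy, and a
#' detected contig exists at least once.
#'
#' @param contig_ids Called contig ids (non-empty).
#' @param copy_numbers Estimated copy numbers, same order.
#' @param lengths_bp Contig lengths in bp, same order.
#' @return List with `total_adjusted_bp` and `per_contig_adjusted_bp`
#'   (named numeric).
#' @export
estimate_total_grc_length <- function(contig_ids, copy_numbers, lengths_bp) {
  stopifnot(length(contig_ids) >= 1,
            length(copy_numbers) == length(contig_ids),
            length(lengths_bp) == length(contig_ids))
  adj <- as.numeric(lengths_bp) * pmax(1, copy_numbers)
  names(adj) <- contig_ids
  list(total_adjusted_bp = sum(adj), per_contig_adjusted_bp = adj)
}

#' Assign the three germline-restricted sequence categories
#'
#' Called contigs split into `high_copy` (estimated copy number >= 2:
#' fold change driven by the germline numerator) and
#' `low_copy_divergent` (near-zero somatic FPKM: fold change driven by
#' the denominator, the pattern of a divergent single-copy paralog).
#' Contigs that miss the high-confidence thresholds but sit in the
#' `similar_band` of fold change at significant q are `low_copy_similar`
#' — the 3:2 germline:soma expectation of one germline allele collapsed
#' onto two A-chromosome alleles. Called contigs fitting neither rule
#' are `ambiguous`; everything else is `not_grc`.
#'
#' @param diff Differential data.frame (tested rows only).
#' @param copy_numbers Estimated copy numbers per row of `diff`.
#' @param thresholds A [threshold_set()].
#' @param soma_fpkm_floor Near-zero somatic FPKM ceiling for the
#'   divergent class (default 1 FPKM).
#' @param similar_band Fold-change interval `[low, high)` for the
#'   similar class; default `c(1.2, 2.0)` brackets the 3:2 = 1.5
#'   expectation below the high-confidence cutoff.
#' @return A data.frame `contig_id`, `is_hcgrc`, `category`,
#'   `est_copy_number`.
#' @export
categorize <- function(diff, copy_numbers, thresholds = threshold_set(),
                       soma_fpkm_floor = 1.0,
                       similar_band = c(1.2, 2.0)) {
  stopifnot(length(copy_numbers) == nrow(diff),
            length(similar_band) == 2, similar_band[1] < similar_band[2])
  hc <- classify_hcgrc(diff, thresholds)
  category <- rep("not_grc", nrow(diff))
  category[hc & copy_numbers >= 2] <- "high_copy"
  category[hc & copy_numbers < 2 &
             diff$mean_fpkm_soma < soma_fpkm_floor] <- "low_copy_divergent"
  category[hc & copy_numbers < 2 &
             diff$mean_fpkm_soma >= soma_fpkm_floor] <- "ambiguous"
  in_band <- !hc & diff$fold_change >= similar_band[1] &
    diff$fold_change < similar_band[2] & diff$q_value < thresholds$max_q
  category[in_band] <- "low_copy_similar"
  data.frame(contig_id = diff$contig_id, is_hcgrc = hc,
             category = category, est_copy_number = copy_numbers,
             stringsAsFactors = FALSE, row.names = NULL)
}
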