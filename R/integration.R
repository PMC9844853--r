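# Integration of cistromes with differential expression: DEG thresholding,
# target-set shift tests, distance-to-TSS summaries, and the TF-by-TF
# target-network tabulation.

#' Threshold a DE table into down- and up-regulated gene sets
#'
#' A gene is called down-regulated when its signed linear fold change is
#' `<= -fc_threshold` and its adjusted p-value is `< fdr_threshold`
#' (up-regulated symmetrically). The defaults (|FC| > 1.5, FDR < 5%) are the
#' conventional knockdown-screen cutoffs. Genes with missing fold change or
#' adjusted p are excluded from both sets; their number is reported and a
#' warning is raised when any are dropped.
#'
#' @param de A DE table (see [de_table()]).
#' @param fc_threshold Linear fold-change threshold (> 1, default 1.5).
#' @param fdr_threshold Adjusted-p threshold in (0, 1), default 0.05.
#' @return A list with sorted character vectors `down` and `up`, and
#'   `n_excluded`, the number of genes dropped for missing values.
#' @export
filter_degs <- function(de, fc_threshold = 1.5, fdr_threshold = 0.05) {
  .need_cols(de, c("gene_id", "fc", "padj"), "DE table")
  if (fc_threshold <= 1) .stopf("fc_threshold must be > 1 (linear scale)")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    .stopf("fdr_threshold must be in (0, 1)")
  ok <- !is.na(de$fc) & !is.na(de$padj)
  n_excluded <- sum(!ok)
  if (n_excluded > 0L)
    .warnf("%d gene(s) with missing FC or adjusted p excluded from filtering",
           n_excluded)
  d <- de[ok, , drop = FALSE]
  list(down = sort(d$gene_id[d$fc <= -fc_threshold & d$padj < fdr_threshold]),
       up = sort(d$gene_id[d$fc >= fc_threshold & d$padj < fdr_threshold]),
       n_excluded = n_excluded)
}

#' Test a target gene set for a fold-change shift
#'
#' Rank-based test of whether a TF's putative direct targets are shifted in
#' expression response relative to the rest of the transcriptome. The default
#' two-sample mode is a Wilcoxon rank-sum test of target vs non-target log2
#' fold changes; the one-sample mode is a Wilcoxon signed-rank test of target
#' log2 fold changes against zero. Exact p-values are used for sample sizes
#' up to 25 (ties permitting), the continuity-corrected normal approximation
#' above that. Genes with missing log2 fold change are dropped; genes with
#' missing adjusted p are retained (the shift test uses only fold changes).
#'
#' @param de A DE table.
#' @param targets Character vector of target gene ids; at least 5 must be
#'   present in the table.
#' @param mode `"two-sample"` (default) or `"one-sample"`.
#' @param alternative Passed to [stats::wilcox.test()]; default two-sided.
#' @return A list: `statistic`, `p_value`, `median_target`,
#'   `median_background` (NA in one-sample mode), `n_target`,
#'   `n_background`, `mode`.
#' @export
target_shift_test <- function(de, targets, mode = c("two-sample", "one-sample"),
                              alternative = "two.sided") {
  mode <- match.arg(mode)
  .need_cols(de, c("gene_id", "log2fc"), "DE table")
  de <- de[!is.na(de$log2fc), , drop = FALSE]
  is_t <- de$gene_id %in% targets
  x <- de$log2fc[is_t]
  if (length(x) < 5L)
    .stopf("only %d target gene(s) found in the DE table (need >= 5)", length(x))
  if (mode == "two-sample") {
    y <- de$log2fc[!is_t]
    if (!length(y)) .stopf("no non-target genes in the DE table")
    if (length(unique(c(x, y))) == 1L)
      .stopf("all fold changes are tied; shift test undefined")
    exact <- length(x) <= 25L && length(y) <= 25L
    ht <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = exact,
                  correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         median_target = median(x), median_background = median(y),
         n_target = length(x), n_background = length(y), mode = mode)
  } else {
    if (length(unique(x)) == 1L && x[1L] == 0)
      .stopf("all fold changes are tied at zero; shift test undefined")
    exact <- length(x) <= 25L
    ht <- suppressWarnings(
      wilcox.test(x, mu = 0, alternative = alternative, exact = exact,
                  correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         median_target = median(x), median_background = NA_real_,
         n_target = length(x), n_background = 0L, mode = mode)
  }
}

#' Summarise peak-to-TSS distances
#'
#' @param annotated Output of [nearest_tss()] (flagged no-TSS rows are
#'   dropped with a warning).
#' @param breaks Histogram bin edges over distance (half-open bins,
#'   right-open); default log10-spaced decades to 10 Mbp plus an overflow
#'   bin.
#' @return A list: `mean`, `median`, `n`, and `histogram` (data frame of
#'   `lower`, `upper`, `count`).
#' @export
distance_stats <- function(annotated,
                           breaks = c(0, 10^seq(0, 7, length.out = 10), Inf)) {
  .need_cols(annotated, c("distance", "no_tss"), "annotated peaks")
  if (any(annotated$no_tss)) {
    .warnf("%d peak(s) on contigs with no TSS dropped from distance stats",
           sum(annotated$no_tss))
    annotated <- annotated[!annotated$no_tss, , drop = FALSE]
  }
  d <- annotated$distance
  if (!length(d)) .stopf("no annotated peaks with a defined distance")
  if (is.unsorted(breaks, strictly = TRUE)) .stopf("breaks must be strictly increasing")
  bin <- findInterval(d, breaks)
  count <- tabulate(bin, nbins = length(breaks) - 1L)
  list(mean = mean(d), median = median(d), n = length(d),
       histogram = data.frame(lower = breaks[-length(breaks)],
                              upper = breaks[-1L], count = count))
}

#' Tabulate down-regulated genes against two TFs' proximal target sets
#'
#' Builds the direct-target intersection report: of the genes down-regulated
#' on knockdown, how many lie nearest to a peak of TF A, of TF B, and of
#' both. All cells are exact set intersections over the shared gene-id
#' namespace.
#'
#' @param down_genes Character vector of down-regulated gene ids.
#' @param tfA_targets,tfB_targets Character vectors of gene ids assigned to
#'   each TF's peaks (e.g. unique `gene_id` from [nearest_tss()]).
#' @param up_genes Optional up-regulated set, carried through for reporting.
#' @param tfA,tfB Labels for the two factors.
#' @return An object of class `"target_set_report"`: counts `n_down`,
#'   `n_up`, `n_down_tfA`, `n_down_tfB`, `n_down_both`, and the sorted gene
#'   lists `down_tfA`, `down_tfB`, `down_both`, `down_neither`.
#' @export
build_network_report <- function(down_genes, tfA_targets, tfB_targets,
                                 up_genes = character(0),
                                 tfA = "tfA", tfB = "tfB") {
  down <- sort(unique(as.character(down_genes)))
  a <- intersect(down, tfA_targets)
  b <- intersect(down, tfB_targets)
  both <- intersect(a, b)
  structure(list(tfA = tfA, tfB = tfB,
                 n_down = length(down), n_up = length(unique(up_genes)),
                 n_down_tfA = length(a), n_down_tfB = length(b),
                 n_down_both = length(both),
                 down_tfA = sort(a), down_tfB = sort(b),
                 down_both = sort(both),
                 down_neither = sort(setdiff(down, union(a, b)))),
            class = "target_set_report")
}

#' @export
print.target_set_report <- function(x, ...) {
  cat(sprintf("Target-set report (%s vs %s)\n", x$tfA, x$tfB))
  cat(sprintf("  down-regulated genes: %d (up: %d)\n", x$n_down, x$n_up))
  cat(sprintf("  with %s peak nearby:  %d (%.0f%%)\n", x$tfA, x$n_down_tfA,
              100 * x$n_down_tfA / max(1L, x$n_down)))
  cat(sprintf("  with %s peak nearby:  %d (%.0f%%)\n", x$tfB, x$n_down_tfB,
              100 * x$n_down_tfB / max(1L, x$n_down)))
  cat(sprintf("  with both:            %d\n", x$n_down_both))
  invisible(x)
}
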