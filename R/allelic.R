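# Allelic imbalance at a heterozygous regulatory SNP: read filtering,
# per-donor allele counting, exact two-sided binomial test against 1:1, and
# Fisher combination across donors.

#' Construct read records covering a SNP
#'
#' A minimal alignment-record model sufficient for allele counting: one row
#' per read with its mapping quality, duplicate/proper-pair flags and the
#' base it carries at the query SNP.
#'
#' @param contig,pos Read position (informational).
#' @param mapq Mapping quality (>= 0).
#' @param is_duplicate,is_proper_pair Logical flags.
#' @param base Base at the SNP: `A`, `C`, `G`, `T` or `N`.
#' @param donor Optional donor id.
#' @return A data frame of read records.
#' @export
read_records <- function(contig, pos, mapq, is_duplicate, is_proper_pair,
                         base, donor = NA_character_) {
  base <- toupper(as.character(base))
  if (any(!base %in% c("A", "C", "G", "T", "N")))
    .stopf("read base must be one of A, C, G, T, N")
  if (any(mapq < 0)) .stopf("mapq must be >= 0")
  n <- length(base)
  data.frame(donor = rep_len(as.character(donor), n),
             contig = rep_len(as.character(contig), n),
             pos = rep_len(as.integer(pos), n),
             mapq = rep_len(as.integer(mapq), n),
             is_duplicate = rep_len(as.logical(is_duplicate), n),
             is_proper_pair = rep_len(as.logical(is_proper_pair), n),
             base = base, stringsAsFactors = FALSE)
}

#' Read a SAM-subset read table (TSV with header)
#'
#' Columns: `donor`, `contig`, `pos`, `mapq`, `is_duplicate`,
#' `is_proper_pair`, `base`.
#' @param path File path.
#' @return A read-record data frame.
#' @export
read_allele_reads <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .need_cols(df, c("contig", "pos", "mapq", "is_duplicate", "is_proper_pair",
                   "base"), "read table")
  if (!"donor" %in% names(df)) df$donor <- NA_character_
  read_records(df$contig, df$pos, df$mapq, df$is_duplicate,
               df$is_proper_pair, df$base, df$donor)
}

#' Read a bare allele-counts table (TSV with header)
#'
#' Columns: `donor`, `n_ref`, `n_alt` — one row per donor, ready for
#' [ai_test()] when counts were produced outside the package.
#' @param path File path.
#' @return An allele-counts data frame.
#' @export
read_allele_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .need_cols(df, c("donor", "n_ref", "n_alt"), "allele-counts table")
  if (any(df$n_ref < 0 | df$n_alt < 0)) .stopf("negative allele counts")
  df$n_ref <- as.integer(df$n_ref)
  df$n_alt <- as.integer(df$n_alt)
  df
}

#' Filter reads for allele counting
#'
#' Retains reads that are not duplicates, are properly paired, and have
#' mapping quality at least `mapq_min` — the standard pre-filter before
#' counting allele-informative reads (a read with MAPQ exactly at the
#' threshold is kept). Input order is preserved.
#'
#' @param reads A read-record data frame.
#' @param mapq_min Minimum mapping quality (default 10).
#' @return The retained subset, same columns, original order.
#' @export
filter_reads <- function(reads, mapq_min = 10L) {
  .need_cols(reads, c("mapq", "is_duplicate", "is_proper_pair"), "reads")
  keep <- !reads$is_duplicate & reads$is_proper_pair & reads$mapq >= mapq_min
  reads[keep, , drop = FALSE]
}

#' Count ref and alt reads at a SNP
#'
#' @param reads Filtered read records.
#' @param snp A one-row SNP record.
#' @param donor Donor label for the returned counts (defaults to the reads'
#'   donor when unique).
#' @return A one-row data frame: `donor`, `n_ref`, `n_alt`, `n_other`
#'   (reads carrying neither allele or N, excluded from testing).
#' @export
count_alleles <- function(reads, snp, donor = NULL) {
  .need_cols(reads, "base", "reads")
  .need_cols(snp, c("ref", "alt"), "SNP record")
  stopifnot(nrow(snp) == 1L)
  if (is.null(donor)) {
    d <- unique(reads$donor)
    donor <- if (length(d) == 1L) d else NA_character_
  }
  data.frame(donor = donor,
             n_ref = sum(reads$base == snp$ref),
             n_alt = sum(reads$base == snp$alt),
             n_other = sum(!reads$base %in% c(snp$ref, snp$alt)),
             stringsAsFactors = FALSE)
}

#' Exact two-sided binomial test for allelic imbalance
#'
#' Tests `n_ref` ref reads out of `n_ref + n_alt` informative reads against
#' the null ref-allele probability `p0` (1:1 expectation by default). The
#' two-sided p-value follows the minimum-likelihood convention: the sum of
#' `P(X = k)` over every outcome no more probable than the observed one.
#' Cross-checked against [stats::binom.test()], which uses the same
#' convention.
#'
#' @param n_ref,n_alt Nonnegative allele read counts (at least one read in
#'   total).
#' @param p0 Null ref-allele probability (default 0.5).
#' @return The two-sided p-value.
#' @examples
#' binomial_ai_test(15, 5)   # 0.0414
#' binomial_ai_test(12, 4)   # 0.0768
#' @export
binomial_ai_test <- function(n_ref, n_alt, p0 = 0.5) {
  if (n_ref < 0 || n_alt < 0) .stopf("negative allele counts")
  n <- n_ref + n_alt
  if (n < 1) .stopf("no informative reads")
  if (p0 <= 0 || p0 >= 1) .stopf("p0 must be in (0, 1)")
  d <- dbinom(0:n, n, p0)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(d[d <= d[n_ref + 1L] * (1 + 1e-7)]))
}

#' Combine independent p-values by Fisher's method
#'
#' `statistic = -2 * sum(log(p))`, referred to the upper tail of a
#' chi-square distribution with `2k` degrees of freedom.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return A list: `statistic`, `df`, `p_value`.
#' @examples
#' fisher_combine(c(0.0414, 0.0768))
#' @export
fisher_combine <- function(pvalues) {
  if (!length(pvalues)) .stopf("no p-values to combine")
  if (any(is.na(pvalues) | pvalues <= 0 | pvalues > 1))
    .stopf("all p-values must lie in (0, 1]")
  stat <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Allelic-imbalance test across donors
#'
#' Runs the exact two-sided binomial test per donor and combines the
#' per-donor p-values by Fisher's method.
#'
#' @param counts An allele-counts data frame (`donor`, `n_ref`, `n_alt`; one
#'   row per donor), e.g. rows from [count_alleles()].
#' @param p0 Null ref-allele probability (default 0.5).
#' @return An object of class `"ai_result"`: `per_donor` (the counts with a
#'   `p_value` column), `statistic`, `df`, `p_value` (combined).
#' @export
ai_test <- function(counts, p0 = 0.5) {
  .need_cols(counts, c("n_ref", "n_alt"), "allele counts")
  if (!nrow(counts)) .stopf("no donors")
  pv <- vapply(seq_len(nrow(counts)), function(i)
    binomial_ai_test(counts$n_ref[i], counts$n_alt[i], p0 = p0), numeric(1))
  comb <- fisher_combine(pv)
  per <- counts
  per$p_value <- pv
  structure(list(per_donor = per, statistic = comb$statistic, df = comb$df,
                 p_value = comb$p_value), class = "ai_result")
}

#' @export
print.ai_result <- function(x, ...) {
  cat("Allelic-imbalance test (per-donor exact binomial + Fisher)\n")
  for (i in seq_len(nrow(x$per_donor))) {
    r <- x$per_donor[i, ]
    cat(sprintf("  %s: %d ref : %d alt, p = %.4f\n",
                if (is.na(r$donor)) sprintf("donor %d", i) else r$donor,
                r$n_ref, r$n_alt, r$p_value))
  }
  cat(sprintf("  combined: chi-square = %.2f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' One-sided sign test for a consistent direction across experiments
#'
#' Probability of at least `n_consistent` same-direction outcomes out of
#' `n_total` under a fair coin: `P(X >= n_consistent)`,
#' `X ~ Binomial(n_total, 0.5)`. When all outcomes agree this is
#' `0.5^n_total`.
#'
#' @param n_consistent,n_total Counts, `0 <= n_consistent <= n_total`,
#'   `n_total >= 1`.
#' @return The one-sided p-value.
#' @examples
#' sign_trend_test(6, 6)   # 0.5^6 = 0.015625
#' @export
sign_trend_test <- function(n_consistent, n_total) {
  if (n_total < 1 || n_consistent < 0 || n_consistent > n_total)
    .stopf("need 0 <= n_consistent <= n_total and n_total >= 1")
  pbinom(n_consistent - 1, n_total, 0.5, lower.tail = FALSE)
}
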