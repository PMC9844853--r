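# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive all-pairs / per-base logic so they stay independent of the
# implementation paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

rand_granges <- function(n, contigs = c("chr1", "chr2"), contig_len = 1000,
                         max_width = 50, summits = FALSE, scores = FALSE) {
  s <- sample.int(contig_len - max_width, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  gr <- GRanges(sample(contigs, n, replace = TRUE), IRanges(s, s + w - 1L))
  if (scores) mcols(gr)$score <- round(runif(n) * 100, 3)
  if (summits) mcols(gr)$summit <- vapply(w, function(x) sample.int(x, 1L) - 1L,
                                          integer(1))
  gr
}

# O(n*m) all-pairs query-side overlap oracle
brute_overlap_count <- function(a, b, min_bp = 1) {
  hit <- vapply(seq_along(a), function(i) {
    any(as.character(seqnames(b)) == as.character(seqnames(a))[i] &
          pmin(end(b), end(a)[i]) - pmax(start(b), start(a)[i]) + 1L >= min_bp)
  }, logical(1))
  list(count = sum(hit), index = which(hit))
}

# exhaustive nearest-gene oracle with the documented tie-break
brute_nearest <- function(contig, anchor, tss) {
  cand <- tss[tss$contig == contig, , drop = FALSE]
  if (!nrow(cand)) return(list(gene_id = NA_character_, distance = NA_real_))
  d <- abs(cand$tss - anchor)
  best <- cand$gene_id[d == min(d)]
  list(gene_id = min(best), distance = min(d))
}

# per-base GC counting oracle
brute_gc <- function(genome, contig, s, e) {
  seq <- strsplit(as.character(subseq(genome[[contig]], s, e)), "")[[1L]]
  acgt <- sum(seq %in% c("A", "C", "G", "T"))
  if (acgt == 0) NA_real_ else sum(seq %in% c("G", "C")) / acgt
}

# minimum-likelihood two-sided binomial by full enumeration
enum_binom_p <- function(k, n, p0 = 0.5) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

toy_tss <- function(...) {
  df <- data.frame(...)
  tss_map(df$gene_id, df$contig, df$tss)
}

# small deterministic genome from explicit sequences
toy_genome <- function(...) {
  seqs <- c(...)
  g <- DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

# read records helper with defaults that pass all filters
pass_reads <- function(base, donor = "d1", mapq = 30, dup = FALSE,
                       proper = TRUE) {
  read_records("chr1", 100L, mapq = rep_len(mapq, length(base)),
               is_duplicate = rep_len(dup, length(base)),
               is_proper_pair = rep_len(proper, length(base)),
               base = base, donor = donor)
}
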