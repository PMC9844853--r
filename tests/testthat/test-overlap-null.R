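# Small, fast checks of the matched-null machinery; the full calibration and
# power studies run in test-acceptance.R.

small_world <- function(seed = 1, overlap = 0, n_a = 40, n_b = 120) {
  cfg <- sim_config(seed, genome = list(contig_length = 2e5, n_tss = 50),
                    peaks = list(n_a = n_a, n_b = n_b,
                                 overlap_fraction = overlap, len_sd = 0))
  w <- gen_genome(cfg)
  pk <- gen_peaksets(cfg, w)
  list(cfg = cfg, w = w, pk = pk)
}

test_that("matching profile assigns every interval to exactly one joint bin", {
  sw <- small_world()
  pr <- build_profile(sw$pk$setA, sw$w$genome, sw$w$tss)
  expect_equal(sum(pr$counts), length(sw$pk$setA))
  expect_length(pr$bin, length(sw$pk$setA))
  # single interval -> one bin of count 1
  pr1 <- build_profile(sw$pk$setA[1], sw$w$genome, sw$w$tss)
  expect_equal(unname(pr1$counts), 1L)
  expect_length(pr1$counts, 1L)
})

test_that("profile binning matches a hand-built cut()-based oracle", {
  g <- toy_genome(chr1 = strrep("AT", 500),      # GC 0
                  chr2 = strrep("GC", 500))      # GC 1
  tss <- tss_map(c("g1", "g2"), c("chr1", "chr2"), c(1L, 1L))
  set.seed(31)
  s <- sample.int(900, 10)
  gr <- GRanges(sample(c("chr1", "chr2"), 10, TRUE), IRanges(s, s + 19L))
  pr <- build_profile(gr, g, tss)
  gc <- gc_content(g, gr)
  mid <- (start(gr) + end(gr)) %/% 2L
  dist <- abs(mid - 1L)
  gcb <- as.integer(cut(gc, pr$gc_breaks, right = FALSE, labels = FALSE))
  gcb[gc == 1] <- length(pr$gc_breaks) - 1L   # closed top bin
  dstb <- as.integer(cut(dist, pr$dist_breaks, right = FALSE, labels = FALSE))
  key <- gcb * 100L + dstb
  expect_equal(sort(pr$bin), sort(key))
  expect_equal(pr$counts[order(as.integer(names(pr$counts)))],
               setNames(as.integer(table(key)[order(as.integer(names(table(key))))]),
                        sort(unique(as.character(key)))))
})

test_that("matched sampling conserves bins, stays in open chromatin, is seeded", {
  sw <- small_world(seed = 2)
  pr <- build_profile(sw$pk$setA, sw$w$genome, sw$w$tss)
  s1 <- sample_matched_set(pr, sw$w$open, sw$w$genome, sw$w$tss, seed = 99)
  s2 <- sample_matched_set(pr, sw$w$open, sw$w$genome, sw$w$tss, seed = 99)
  expect_identical(as.data.frame(s1), as.data.frame(s2))   # determinism
  expect_equal(length(s1), length(sw$pk$setA))             # cardinality
  # containment: every sampled base inside open chromatin
  cov <- GenomicRanges::intersect(s1, sw$w$open, ignore.strand = TRUE)
  expect_equal(sum(width(cov)), sum(width(GenomicRanges::reduce(s1))))
  expect_equal(overlap_count(s1, sw$w$open)$count, length(s1))
  # conservation: joint bin counts of the draw equal the template's exactly
  pr_s <- build_profile(s1, sw$w$genome, sw$w$tss)
  expect_equal(pr_s$counts, pr$counts)
  # lengths drawn from the template length distribution
  expect_true(all(width(s1) %in% pr$lengths))
})

test_that("trivial one-bin matching reduces to plain placement in open chromatin", {
  sw <- small_world(seed = 3, n_a = 25)
  pr <- build_profile(sw$pk$setA, sw$w$genome, sw$w$tss,
                      gc_breaks = c(0, 1), dist_breaks = c(0, Inf))
  expect_length(pr$counts, 1L)
  s <- sample_matched_set(pr, sw$w$open, sw$w$genome, sw$w$tss, seed = 5)
  expect_equal(length(s), 25L)
  expect_equal(overlap_count(s, sw$w$open)$count, 25L)
})

test_that("GC-stratified template forces samples into the matching stratum", {
  # two equal strata at GC 0.3 / 0.7; template entirely in the 0.7 stratum
  cfg <- sim_config(7, genome = list(contig_length = 2e5, n_tss = 50,
                                     gc_strata = c(0.3, 0.7), n_contigs = 1L,
                                     open_fraction = 0.5))
  w <- gen_genome(cfg)
  hi <- w$strata[mcols(w$strata)$target_gc == 0.7]
  open_hi <- GenomicRanges::intersect(w$open, hi, ignore.strand = TRUE)
  set.seed(8)
  wide <- open_hi[width(open_hi) > 300]
  pick <- sample.int(length(wide), 30, replace = TRUE)
  s0 <- start(wide)[pick] +
    vapply(width(wide)[pick] - 200L, function(m) sample.int(m, 1L), integer(1))
  template <- GRanges("chr1", IRanges(s0, s0 + 199L))
  pr <- build_profile(template, w$genome, w$tss)
  drawn <- sample_matched_set(pr, w$open, w$genome, w$tss, seed = 9)
  # drawn intervals may overlap each other, so measure over the distinct
  # covered bases
  in_hi <- sum(width(GenomicRanges::intersect(drawn, hi, ignore.strand = TRUE)))
  expect_gte(in_hi / sum(width(GenomicRanges::reduce(drawn))), 0.95)
})

test_that("unfillable bins raise an informative error", {
  # open chromatin restricted to the low-GC stratum cannot match a
  # high-GC template
  g <- toy_genome(chr1 = paste0(strrep("AT", 5000), strrep("GC", 5000)))
  tss <- tss_map("g1", "chr1", 1L)
  template <- GRanges("chr1", IRanges(15001, 15200))   # pure GC
  open_low <- GRanges("chr1", IRanges(1, 10000))       # pure AT
  pr <- build_profile(template, g, tss)
  expect_error(
    sample_matched_set(pr, open_low, g, tss, seed = 1, max_rejections = 50),
    "could not fill")
})

test_that("permutation test is reproducible and its p-value respects the formula", {
  sw <- small_world(seed = 4, overlap = 0.8, n_a = 30, n_b = 90)
  r1 <- permutation_overlap_test(sw$pk$setA, sw$pk$setB, sw$w$open,
                                 sw$w$genome, sw$w$tss, n_perm = 29, seed = 11)
  r2 <- permutation_overlap_test(sw$pk$setA, sw$pk$setB, sw$w$open,
                                 sw$w$genome, sw$w$tss, n_perm = 29, seed = 11)
  expect_identical(r1$null_draws, r2$null_draws)
  expect_equal(r1$empirical_p,
               (sum(r1$null_draws >= r1$observed) + 1) / (29 + 1))
  expect_gte(r1$empirical_p, 1 / 30)
  expect_lte(r1$empirical_p, 1)
  # fast per-permutation counter agrees with overlap_count
  s <- sample_matched_set(build_profile(sw$pk$setA, sw$w$genome, sw$w$tss),
                          sw$w$open, sw$w$genome, sw$w$tss, seed = 12)
  expect_equal(cistromics:::.count_query_overlaps(
                 cistromics:::.overlap_counter(sw$pk$setB),
                 as.character(seqnames(s)), start(s), end(s)),
               overlap_count(s, sw$pk$setB)$count)

  # n_perm = 1 edge case: strong planted overlap beats one null draw
  r <- permutation_overlap_test(sw$pk$setA, sw$pk$setB, sw$w$open,
                                sw$w$genome, sw$w$tss, n_perm = 1, seed = 13)
  expect_equal(r$empirical_p, 0.5)
})
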