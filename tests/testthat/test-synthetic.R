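test_that("generators are pure functions of the configuration seed", {
  cfg <- sim_config(61, genome = list(contig_length = 5e4, n_tss = 30),
                    peaks = list(n_a = 20, n_b = 60))
  w1 <- gen_genome(cfg); w2 <- gen_genome(cfg)
  expect_identical(as.character(w1$genome), as.character(w2$genome))
  expect_identical(as.data.frame(w1$open), as.data.frame(w2$open))
  expect_identical(w1$tss, w2$tss)
  p1 <- gen_peaksets(cfg, w1); p2 <- gen_peaksets(cfg, w2)
  expect_identical(as.data.frame(p1$setA), as.data.frame(p2$setA))
  snp <- snp_record("rs1", "chr1", 10L, "C", "T")
  r1 <- gen_allelic_reads(cfg, snp); r2 <- gen_allelic_reads(cfg, snp)
  expect_identical(r1$reads, r2$reads)
  # different stage streams are decoupled from one another
  expect_false(substream_seed(61, "genome") == substream_seed(61, "peaks"))
})

test_that("genome strata hit their target GC composition", {
  cfg <- sim_config(62, genome = list(n_contigs = 1L, contig_length = 2e5,
                                      gc_strata = c(0.3, 0.7)))
  w <- gen_genome(cfg)
  gc <- gc_content(w$genome, w$strata)
  expect_equal(gc, mcols(w$strata)$target_gc, tolerance = 0.02)

  # degenerate stratum: all G/C
  cfg1 <- sim_config(63, genome = list(n_contigs = 1L, contig_length = 1e4,
                                       gc_strata = 1.0))
  w1 <- gen_genome(cfg1)
  expect_equal(gc_content(w1$genome, GRanges("chr1", IRanges(1, 1e4))), 1.0)
})

test_that("planted peak overlap is controllable and recorded in the truth", {
  base <- list(contig_length = 2e5, n_tss = 50)
  # fraction 1: every query peak overlaps the reference set
  cfg <- sim_config(64, genome = base,
                    peaks = list(n_a = 40, n_b = 120, overlap_fraction = 1))
  w <- gen_genome(cfg)
  pk <- gen_peaksets(cfg, w)
  expect_equal(overlap_count(pk$setA, pk$setB)$count, 40L)
  # planted peaks are a subset of the observed hit list
  ov <- overlap_count(pk$setA, pk$setB)
  expect_true(all(which(pk$truth$planted) %in% ov$index))
  # every peak lies inside open chromatin
  expect_equal(overlap_count(pk$setA, w$open)$count, 40L)
  expect_equal(overlap_count(pk$setB, w$open)$count, 120L)

  # fraction 0 at the default sparse-reference scale: chance-level overlap
  cfg0 <- sim_config(65, peaks = list(overlap_fraction = 0))
  w0 <- gen_genome(cfg0)
  pk0 <- gen_peaksets(cfg0, w0)
  expect_lt(overlap_count(pk0$setA, pk0$setB)$count, 0.10 * length(pk0$setA))
})

test_that("DE tables carry consistent FC columns and recoverable planted targets", {
  cfg <- sim_config(66)
  ids <- sprintf("gene%03d", 1:300)
  gen <- gen_de_table(cfg, ids)
  # FC = sign * 2^|log2FC| by construction
  expect_equal(gen$de$fc,
               ifelse(gen$de$log2fc >= 0, 2^gen$de$log2fc, -2^(-gen$de$log2fc)))
  r <- filter_degs(gen$de)
  expect_equal(r$down, gen$truth$down)
  expect_equal(r$up, gen$truth$up)

  # effect 0: planted genes have null-sized fold changes -> none pass |FC|>1.5
  cfg0 <- sim_config(67, de = list(effect = 0))
  gen0 <- gen_de_table(cfg0, ids)
  r0 <- filter_degs(gen0$de)
  expect_lte(length(r0$down) + length(r0$up), 2L)
})

test_that("LD-block genotypes have q-tunable within-block correlation", {
  # q = 1: every block SNP copies the latent genotype -> r2 exactly 1
  cfg1 <- sim_config(68, ld = list(q = 1, n_blocks = 1L, block_size = 4L))
  g1 <- gen_genotypes(cfg1)
  for (j in 2:4) expect_equal(ld_r2(g1$g, 1, j), 1.0)

  # mean within-block r2 increases with q
  mean_r2 <- function(q, seed) {
    gen <- gen_genotypes(sim_config(seed, ld = list(q = q, n_blocks = 1L,
                                                    block_size = 6L)))
    idx <- which(gen$truth$block == 1L)
    prs <- combn(idx, 2)
    mean(apply(prs, 2, function(p) ld_r2(gen$g, p[1], p[2])))
  }
  ms <- vapply(c(0.5, 0.7, 0.9), function(q) {
    mean(vapply(1:5, function(s) mean_r2(q, 200 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
  # q = 0: within-block r2 indistinguishable from background noise
  m0 <- mean(vapply(1:5, function(s) mean_r2(0, 300 + s), numeric(1)))
  expect_lt(m0, 0.05)
})

test_that("allele-read generator hits the planted imbalance at depth", {
  snp <- snp_record("rs1", "chr1", 100L, "C", "T")
  cfg <- sim_config(69, ai = list(depth = 10000L, ratio = 1, n_donors = 1L))
  gen <- gen_allelic_reads(cfg, snp)
  frac <- gen$truth$n_ref / (gen$truth$n_ref + gen$truth$n_alt)
  expect_equal(frac, 0.5, tolerance = 0.02)
  cfg3 <- sim_config(70, ai = list(depth = 10000L, ratio = 3, n_donors = 1L))
  gen3 <- gen_allelic_reads(cfg3, snp)
  frac3 <- gen3$truth$n_ref / (gen3$truth$n_ref + gen3$truth$n_alt)
  expect_equal(frac3, 0.75, tolerance = 0.02)
})

test_that("simulate_study assembles a coherent end-to-end toy study", {
  p <- read_pwm(system.file("extdata", "lhx2_like_synthetic.jaspar",
                            package = "cistromics"))
  cfg <- sim_config(71, genome = list(contig_length = 2e5, n_tss = 80),
                    peaks = list(n_a = 40, n_b = 120, overlap_fraction = 0.65))
  st <- simulate_study(cfg, pwm = p)
  # co-occupancy planted well above chance
  ov <- overlap_count(st$peaks$setA, st$peaks$setB)
  expect_gte(ov$count, st$truth$peaks$n_planted)
  # DEG filter recovers the planted targets, which sit near co-occupied peaks
  r <- filter_degs(st$de)
  expect_equal(r$down, st$truth$de$down)
  expect_true(all(st$truth$de$down %in%
                    st$annotated_a$gene_id[ov$index]))
  # the planted risk SNP lies inside both cistromes
  hit <- intersect_snps_peaks(st$snp, list(a = st$peaks$setA, b = st$peaks$setB))
  expect_equal(hit$hits, "rs_sim1")
  # and the alt allele disrupts the embedded consensus motif
  eff <- scan_allele_effect(p, st$world$genome, st$snp, flank = p$width + 2L)
  expect_lt(eff$delta, 0)
  # the AI stage shows the planted 3:1 imbalance direction
  expect_true(all(st$ai$truth$n_ref > st$ai$truth$n_alt))
  # targets shift test flags the planted down-set
  expect_lt(target_shift_test(st$de, st$truth$de$down)$p_value, 1e-6)
})
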