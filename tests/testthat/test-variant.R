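toy_gm <- function(dosages) {
  n <- ncol(dosages)
  genotype_matrix(dosages, snp_record(sprintf("s%02d", 1:n), "chr1",
                                      (1:n) * 1000L, "A", "G"))
}

test_that("ld_r2 is a symmetric, encoding-invariant squared correlation", {
  set.seed(41)
  x <- rbinom(50, 2, 0.4)
  x[1:2] <- c(0L, 2L)                        # guarantee polymorphism
  g <- toy_gm(cbind(x, x, 2L - x, rbinom(50, 2, 0.4)))
  expect_equal(ld_r2(g, 1, 2), 1.0)
  expect_equal(ld_r2(g, 1, 3), 1.0)          # anti-correlated dosages
  expect_equal(ld_r2(g, 1, 4), ld_r2(g, 4, 1))
  expect_equal(ld_r2(g, "s01", "s04"), ld_r2(g, 1, 4))

  # independent SNPs at large n have near-zero r2
  set.seed(42)
  for (i in 1:5) {
    gg <- toy_gm(cbind(rbinom(10000, 2, 0.5), rbinom(10000, 2, 0.5)))
    expect_lt(ld_r2(gg, 1, 2), 0.01)
  }

  # monomorphic and missing-data failures are distinct
  gm <- toy_gm(cbind(rep(1L, 10), rbinom(10, 2, 0.5)))
  expect_error(ld_r2(gm, 1, 2), "monomorphic")
  dos <- cbind(c(0L, rep(NA, 9L)), c(rep(NA, 9L), 2L))
  expect_error(ld_r2(toy_gm(dos), 1, 2), "non-missing")
})

test_that("expand_tag_snps recovers planted LD blocks and is threshold-monotone", {
  cfg <- sim_config(43)
  gen <- gen_genotypes(cfg)
  tag <- gen$g$snps$id[gen$truth$block == 1L][1L]
  got <- expand_tag_snps(tag, gen$g)
  expect_setequal(got$id, gen$g$snps$id[gen$truth$block == 1L])
  expect_true(got$is_tag[got$id == tag])

  # a second tag in the same block leaves the union unchanged
  tag2 <- gen$g$snps$id[gen$truth$block == 1L][2L]
  got2 <- expand_tag_snps(c(tag, tag2), gen$g)
  expect_setequal(got2$id, got$id)

  # monotone: raising the threshold never grows the set
  loose <- expand_tag_snps(tag, gen$g, r2_threshold = 0.3)
  strict <- expand_tag_snps(tag, gen$g, r2_threshold = 0.95)
  expect_true(all(strict$id %in% got$id))
  expect_true(all(got$id %in% loose$id))

  # a tag with no mates above threshold returns itself alone
  solo <- gen$g$snps$id[gen$truth$block == 0L][1L]
  expect_equal(expand_tag_snps(solo, gen$g)$id, solo)

  expect_error(expand_tag_snps("nope", gen$g), "nope")
})

test_that("SNP-by-peak membership honours half-open BED semantics and the oracle", {
  # BED record chr1 [0, 100): last covered base is 0-based 99 = 1-based 100
  tmp <- withr::local_tempfile()
  writeLines("chr1\t0\t100", tmp)
  peak <- read_intervals(tmp, "bed")
  snps <- snp_record(c("at_end", "inside"), "chr1", c(101L, 100L), "A", "G")
  r <- intersect_snps_peaks(snps, list(tf = peak))
  expect_equal(r$membership$tf, c(FALSE, TRUE))

  set.seed(44)
  snps <- snp_record(sprintf("rs%03d", 1:304), sample(c("chr1", "chr2"), 304, TRUE),
                     sample.int(1000, 304, replace = TRUE), "C", "T")
  cis <- list(a = rand_granges(15), b = rand_granges(15))
  r <- intersect_snps_peaks(snps, cis)
  for (i in seq_len(nrow(snps))) {
    for (nm in c("a", "b")) {
      want <- any(as.character(seqnames(cis[[nm]])) == snps$contig[i] &
                    start(cis[[nm]]) <= snps$pos[i] & snps$pos[i] <= end(cis[[nm]]))
      expect_identical(r$membership[[nm]][i], want)
    }
  }
  expect_equal(r$hits, r$membership$id[r$membership$a & r$membership$b])
})

test_that("scan_allele_effect reproduces the hand-computed toy delta", {
  # width-2 PWM: P(A)=0.97 at pos 1, P(C)=0.97 at pos 2, else 0.01
  p <- pwm(matrix(c(97, 1, 1, 1, 1, 97, 1, 1), 4), pseudocount = 0)
  g <- toy_genome(chr1 = "TTAACGTT")
  snp <- snp_record("toy", "chr1", 5L, "C", "T")
  eff <- scan_allele_effect(p, g, snp, flank = 2)
  expect_equal(eff$ref_score, 2 * log2(0.97 / 0.25), tolerance = 1e-12)
  # C -> T at motif position 2: delta = log2(.01/.25) - log2(.97/.25)
  expect_equal(eff$delta, log2(0.01 / 0.25) - log2(0.97 / 0.25),
               tolerance = 1e-9)
  expect_equal(round(eff$delta, 2), -6.60)
  # same window maximises both alleles here, so both modes agree
  effm <- scan_allele_effect(p, g, snp, flank = 2, mode = "max")
  expect_equal(effm$delta, eff$delta)
  # flank shorter than the PWM is rejected
  expect_error(scan_allele_effect(p, g, snp, flank = 1), "flank")
  # genome base must match one of the alleles
  expect_error(scan_allele_effect(p, g, snp_record("x", "chr1", 5L, "A", "G")),
               "matches neither")
})

test_that("max-mode delta is antisymmetric under allele swap", {
  set.seed(45)
  for (i in 1:20) {
    p <- pwm(matrix(runif(4 * 5), 4), pseudocount = 0.8)
    seq <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    g <- toy_genome(chr1 = seq)
    pos <- 15L
    ref <- substr(seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    fwd <- scan_allele_effect(p, g, snp_record("s", "chr1", pos, ref, alt),
                              flank = 8, mode = "max")
    rev <- scan_allele_effect(p, g, snp_record("s", "chr1", pos, alt, ref),
                              flank = 8, mode = "max")
    expect_equal(fwd$delta, -rev$delta, tolerance = 1e-12)
  }
})

test_that("a consensus-breaking allele scores a negative delta on the homeobox-like PWM", {
  pwm_path <- system.file("extdata", "lhx2_like_synthetic.jaspar",
                          package = "cistromics")
  p <- read_pwm(pwm_path)
  consensus <- c("A", "C", "G", "T")[apply(p$prob, 2, which.max)]
  # genome context: consensus site embedded mid-sequence
  seq <- paste0(strrep("G", 12), paste(consensus, collapse = ""), strrep("G", 12))
  g <- toy_genome(chr1 = seq)
  at <- 3L                                   # a strongly constrained position
  pos <- 12L + at
  ref <- consensus[at]
  alt <- c("A", "C", "G", "T")[which.min(p$prob[, at])]
  eff <- scan_allele_effect(p, g, snp_record("rs_syn", "chr1", pos, ref, alt),
                            flank = p$width + 2L)
  expect_lt(eff$delta, 0)
  expect_gt(eff$ref_score, eff$alt_score)
})
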