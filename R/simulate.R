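# Seeded generators for every input the pipeline consumes, each with a
# planted ground-truth record. All randomness derives from one master seed,
# split per stage with substream_seed(), so generators are pure functions of
# the configuration and adding a stage never perturbs earlier streams.

#' Simulation configuration
#'
#' Builds the full configuration for the synthetic-study generators, merging
#' user overrides into the defaults. The defaults emulate the statistical
#' structure of a two-factor RPE cistrome study at toy scale: a 2 x 2 Mbp
#' genome with two GC strata, open chromatin covering 60% arranged so that a
#' random query peak has chance-level co-occupancy near 8% (the regime of a
#' sparse reference cistrome in real open chromatin), a 65% planted
#' co-occupancy fraction, knockdown-sized expression effects, tight LD
#' blocks, and 3:1 allelic imbalance at ATAC-scale read depth.
#'
#' @param seed Mandatory integer master seed; there is no hidden entropy.
#' @param genome,peaks,de,ld,ai Named lists overriding individual defaults;
#'   see the package vignette for the meaning and units of every field.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed, genome = list(), peaks = list(), de = list(),
                       ld = list(), ai = list()) {
  if (missing(seed)) .stopf("seed is mandatory")
  defaults <- list(
    genome = list(n_contigs = 2L, contig_length = 2e6, gc_strata = c(0.35, 0.55),
                  open_fraction = 0.6, open_width = 2000L, n_tss = 300L),
    peaks = list(n_a = 150L, n_b = 450L, overlap_fraction = 0.65,
                 len_mean = 200, len_sd = 25, len_min = 50L),
    de = list(n_down = 30L, n_up = 10L, effect = 3, noise_sd = 0.3),
    ld = list(n_blocks = 2L, block_size = 8L, q = 0.975, n_samples = 200L,
              n_unlinked = 20L, maf_range = c(0.2, 0.5)),
    ai = list(depth = 20L, ratio = 3, n_donors = 2L, flagged_fraction = 0.1,
              other_fraction = 0.02))
  merge1 <- function(d, u) { d[names(u)] <- u; d }
  cfg <- list(seed = as.integer(seed),
              genome = merge1(defaults$genome, genome),
              peaks = merge1(defaults$peaks, peaks),
              de = merge1(defaults$de, de),
              ld = merge1(defaults$ld, ld),
              ai = merge1(defaults$ai, ai))
  if (any(cfg$genome$gc_strata < 0 | cfg$genome$gc_strata > 1))
    .stopf("gc_strata must be fractions in [0, 1]")
  if (cfg$peaks$overlap_fraction < 0 || cfg$peaks$overlap_fraction > 1)
    .stopf("overlap_fraction must be in [0, 1]")
  if (cfg$ai$ratio <= 0) .stopf("imbalance ratio must be > 0")
  structure(cfg, class = "sim_config")
}

.random_dna <- function(n, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE, prob = probs)],
        collapse = "")
}

#' Generate a synthetic genome with open chromatin and TSS annotation
#'
#' Each contig is composed of equal-length GC strata at the configured
#' compositions; open chromatin is a random set of fixed-width tiles
#' covering the configured fraction of the genome (adjacent tiles merged);
#' TSS positions are uniform. Deterministic in the configuration seed.
#'
#' @param cfg A `"sim_config"`.
#' @return A list: `genome` (`DNAStringSet`), `open` (`GRanges`), `tss`
#'   (TSS map), `strata` (`GRanges` of stratum spans with a `target_gc`
#'   column).
#' @export
gen_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- cfg$genome
  set.seed(substream_seed(cfg$seed, "genome"))
  L <- as.integer(g$contig_length)
  n_strata <- length(g$gc_strata)
  seg <- floor(L / n_strata)
  contigs <- character(g$n_contigs)
  strata_list <- list()
  for (i in seq_len(g$n_contigs)) {
    parts <- character(n_strata)
    for (k in seq_len(n_strata)) {
      len_k <- if (k < n_strata) seg else L - seg * (n_strata - 1L)
      parts[k] <- .random_dna(len_k, g$gc_strata[k])
      strata_list[[length(strata_list) + 1L]] <-
        data.frame(contig = sprintf("chr%d", i),
                   start = (k - 1L) * seg + 1L,
                   end = if (k < n_strata) k * seg else L,
                   target_gc = g$gc_strata[k])
    }
    contigs[i] <- paste(parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- sprintf("chr%d", seq_len(g$n_contigs))
  # open chromatin: sampled fixed-width tiles
  oc_contig <- character(0); oc_start <- integer(0)
  for (i in seq_len(g$n_contigs)) {
    n_tiles <- L %/% g$open_width
    k <- max(1L, round(g$open_fraction * n_tiles))
    if (k > n_tiles) .stopf("open_fraction infeasible at this tile width")
    idx <- sort(sample.int(n_tiles, k))
    oc_contig <- c(oc_contig, rep(sprintf("chr%d", i), k))
    oc_start <- c(oc_start, (idx - 1L) * g$open_width + 1L)
  }
  open <- GenomicRanges::reduce(GenomicRanges::GRanges(
    oc_contig, IRanges::IRanges(oc_start, oc_start + g$open_width - 1L)))
  sdf <- do.call(rbind, strata_list)
  strata <- GenomicRanges::GRanges(sdf$contig, IRanges::IRanges(sdf$start, sdf$end),
                                   target_gc = sdf$target_gc)
  ctg <- sprintf("chr%d", sample.int(g$n_contigs, g$n_tss, replace = TRUE))
  tss <- tss_map(sprintf("gene%04d", seq_len(g$n_tss)), ctg,
                 sample.int(L, g$n_tss, replace = TRUE),
                 sample(c("+", "-"), g$n_tss, replace = TRUE))
  list(genome = genome, open = open, tss = tss, strata = strata)
}

# place intervals of the given lengths uniformly within open chromatin
# (uniform over open bases, rejected unless fully contained in one open
# interval); returns start/end plus the index of the containing interval
.place_in_open <- function(open_df, cum0, total, lengths) {
  n <- length(lengths)
  out_s <- integer(n); out_j <- integer(n)
  todo <- seq_len(n)
  guard <- 0L
  while (length(todo)) {
    guard <- guard + 1L
    if (guard > 10000L)
      .stopf("cannot place %d interval(s) in open chromatin (lengths too large?)",
             length(todo))
    m <- length(todo)
    u <- runif(m) * total
    j <- findInterval(u, cum0, rightmost.closed = TRUE)
    j[j < 1L] <- 1L; j[j > nrow(open_df)] <- nrow(open_df)
    s <- open_df$start[j] + as.integer(floor(u - cum0[j]))
    ok <- s + lengths[todo] - 1L <= open_df$end[j]
    out_s[todo[ok]] <- s[ok]
    out_j[todo[ok]] <- j[ok]
    todo <- todo[!ok]
  }
  list(start = out_s, open_idx = out_j)
}

#' Generate two peak sets with a planted co-occupancy fraction
#'
#' The reference set (`setB`) is placed uniformly within open chromatin. A
#' configured fraction of query (`setA`) intervals is planted to overlap a
#' randomly chosen `setB` interval by at least 1 bp (while staying inside
#' the same open-chromatin interval); the remainder are placed
#' independently. The truth record marks which `setA` intervals were
#' planted.
#'
#' @param cfg A `"sim_config"`.
#' @param world Output of [gen_genome()].
#' @return A list: `setA`, `setB` (`GRanges`), `truth` (list with logical
#'   `planted` per `setA` interval and the partner index `partner`).
#' @export
gen_peaksets <- function(cfg, world) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$peaks
  set.seed(substream_seed(cfg$seed, "peaks"))
  open_df <- data.frame(contig = as.character(seqnames(world$open)),
                        start = start(world$open), end = end(world$open),
                        stringsAsFactors = FALSE)
  w <- as.numeric(width(world$open))
  cum0 <- c(0, cumsum(w)); total <- sum(w)
  draw_len <- function(n) pmax(p$len_min,
                               pmin(max(width(world$open)) - 1L,
                                    round(rnorm(n, p$len_mean, p$len_sd))))
  len_b <- draw_len(p$n_b)
  pb <- .place_in_open(open_df, cum0, total, len_b)
  setB <- GenomicRanges::GRanges(open_df$contig[pb$open_idx],
                                 IRanges::IRanges(pb$start, pb$start + len_b - 1L))
  n_planted <- round(p$overlap_fraction * p$n_a)
  len_a <- draw_len(p$n_a)
  planted <- c(rep(TRUE, n_planted), rep(FALSE, p$n_a - n_planted))
  partner <- rep(NA_integer_, p$n_a)
  s_a <- integer(p$n_a); ctg_a <- character(p$n_a)
  if (n_planted > 0L) {
    for (i in seq_len(n_planted)) {
      for (try in seq_len(1000L)) {
        j <- sample.int(p$n_b, 1L)
        oj <- pb$open_idx[j]
        lo <- max(open_df$start[oj], start(setB)[j] - len_a[i] + 1L)
        hi <- min(end(setB)[j], open_df$end[oj] - len_a[i] + 1L)
        if (hi >= lo) {
          s_a[i] <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
          ctg_a[i] <- open_df$contig[oj]
          partner[i] <- j
          break
        }
      }
      if (is.na(partner[i]))
        .stopf("could not plant overlap %d: open-chromatin capacity too small", i)
    }
  }
  n_free <- p$n_a - n_planted
  if (n_free > 0L) {
    idx <- (n_planted + 1L):p$n_a
    pa <- .place_in_open(open_df, cum0, total, len_a[idx])
    s_a[idx] <- pa$start
    ctg_a[idx] <- open_df$contig[pa$open_idx]
  }
  setA <- GenomicRanges::GRanges(ctg_a, IRanges::IRanges(s_a, s_a + len_a - 1L))
  list(setA = setA, setB = setB,
       truth = list(planted = planted, partner = partner,
                    n_planted = n_planted))
}

#' Generate a differential-expression table with planted shifts
#'
#' Non-target genes receive null log2 fold changes `N(0, noise_sd)` and
#' non-significant adjusted p-values; planted targets receive the
#' configured shift (down-targets negative, up-targets positive) and small
#' adjusted p-values. The linear fold-change column is derived from log2FC
#' by the sign-preserving convention of [de_table()].
#'
#' @param cfg A `"sim_config"`.
#' @param gene_ids Character universe of gene ids.
#' @param targets_down,targets_up Planted target genes (subsets of
#'   `gene_ids`); defaults take the first `n_down` / next `n_up` genes.
#' @return A list: `de` (DE table), `truth` (list `down`, `up`).
#' @export
gen_de_table <- function(cfg, gene_ids, targets_down = NULL, targets_up = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- cfg$de
  set.seed(substream_seed(cfg$seed, "de"))
  n <- length(gene_ids)
  if (is.null(targets_down)) targets_down <- utils::head(gene_ids, d$n_down)
  if (is.null(targets_up))
    targets_up <- utils::head(setdiff(gene_ids, targets_down), d$n_up)
  if (!all(targets_down %in% gene_ids) || !all(targets_up %in% gene_ids))
    .stopf("planted targets must be a subset of gene_ids")
  log2fc <- rnorm(n, 0, d$noise_sd)
  padj <- runif(n, 0.05, 1)
  idx_dn <- match(targets_down, gene_ids)
  idx_up <- match(targets_up, gene_ids)
  log2fc[idx_dn] <- -abs(d$effect) + rnorm(length(idx_dn), 0, d$noise_sd)
  log2fc[idx_up] <- abs(d$effect) + rnorm(length(idx_up), 0, d$noise_sd)
  padj[c(idx_dn, idx_up)] <- runif(length(idx_dn) + length(idx_up), 0, 1e-4)
  list(de = de_table(gene_ids, log2fc, padj),
       truth = list(down = sort(targets_down), up = sort(targets_up)))
}

#' Generate LD-block genotypes
#'
#' Within a block, each SNP copies a latent block genotype with probability
#' `q` (independently per sample), else draws an independent genotype at the
#' block's allele frequency; between blocks (and for the unlinked filler
#' SNPs) genotypes are independent. The expected within-block pairwise
#' r-squared is approximately `q^4`.
#'
#' @param cfg A `"sim_config"`.
#' @return A list: `g` (a `"genotype_matrix"`), `truth` (list with `block`,
#'   an integer block assignment per SNP, 0 for unlinked).
#' @export
gen_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  l <- cfg$ld
  set.seed(substream_seed(cfg$seed, "ld"))
  n <- l$n_samples
  cols <- list(); ids <- character(0); pos <- integer(0); block <- integer(0)
  for (b in seq_len(l$n_blocks)) {
    maf <- runif(1, l$maf_range[1], l$maf_range[2])
    latent <- rbinom(n, 2L, maf)
    for (k in seq_len(l$block_size)) {
      copy <- runif(n) < l$q
      cols[[length(cols) + 1L]] <- ifelse(copy, latent, rbinom(n, 2L, maf))
      ids <- c(ids, sprintf("blk%d_snp%d", b, k))
      pos <- c(pos, (b - 1L) * 50000L + k * 500L)
      block <- c(block, b)
    }
  }
  for (k in seq_len(l$n_unlinked)) {
    maf <- runif(1, l$maf_range[1], l$maf_range[2])
    cols[[length(cols) + 1L]] <- rbinom(n, 2L, maf)
    ids <- c(ids, sprintf("null_snp%d", k))
    pos <- c(pos, l$n_blocks * 50000L + k * 500L)
    block <- c(block, 0L)
  }
  dos <- do.call(cbind, cols)
  snps <- snp_record(ids, "chr1", pos, "A", "G")
  list(g = genotype_matrix(dos, snps), truth = list(block = block))
}

#' Generate per-donor allele-specific read pileups
#'
#' Per donor, `depth` reads passing all filters carry the ref allele with
#' probability `ratio / (1 + ratio)`; additional reads flagged as duplicates,
#' improperly paired or low-MAPQ (fraction `flagged_fraction` of depth) and
#' reads carrying a third base (fraction `other_fraction`) are appended to
#' exercise the filtering and counting stages. The truth record holds the
#' realised post-filter informative counts.
#'
#' @param cfg A `"sim_config"`.
#' @param snp A one-row SNP record.
#' @return A list: `reads` (list of per-donor read-record data frames),
#'   `truth` (allele-counts data frame, one row per donor).
#' @export
gen_allelic_reads <- function(cfg, snp) {
  stopifnot(inherits(cfg, "sim_config"))
  a <- cfg$ai
  .need_cols(snp, c("contig", "pos", "ref", "alt"), "SNP record")
  set.seed(substream_seed(cfg$seed, "ai"))
  p_ref <- a$ratio / (1 + a$ratio)
  third <- setdiff(c("A", "C", "G", "T"), c(snp$ref, snp$alt))[1L]
  reads <- vector("list", a$n_donors)
  truth <- vector("list", a$n_donors)
  for (d in seq_len(a$n_donors)) {
    donor <- sprintf("donor%d", d)
    base_pass <- ifelse(runif(a$depth) < p_ref, snp$ref, snp$alt)
    pass <- read_records(snp$contig, snp$pos,
                         mapq = sample(30:60, a$depth, replace = TRUE),
                         is_duplicate = FALSE, is_proper_pair = TRUE,
                         base = base_pass, donor = donor)
    n_flag <- round(a$depth * a$flagged_fraction)
    flagged <- NULL
    if (n_flag > 0L) {
      defect <- sample.int(3L, n_flag, replace = TRUE)
      flagged <- read_records(snp$contig, snp$pos,
                              mapq = ifelse(defect == 1L,
                                            sample(0:9, n_flag, replace = TRUE),
                                            sample(30:60, n_flag, replace = TRUE)),
                              is_duplicate = defect == 2L,
                              is_proper_pair = defect != 3L,
                              base = ifelse(runif(n_flag) < p_ref, snp$ref, snp$alt),
                              donor = donor)
    }
    n_other <- round(a$depth * a$other_fraction)
    other <- NULL
    if (n_other > 0L) {
      other <- read_records(snp$contig, snp$pos,
                            mapq = sample(30:60, n_other, replace = TRUE),
                            is_duplicate = FALSE, is_proper_pair = TRUE,
                            base = third, donor = donor)
    }
    all_reads <- rbind(pass, flagged, other)
    all_reads <- all_reads[sample.int(nrow(all_reads)), , drop = FALSE]
    rownames(all_reads) <- NULL
    reads[[d]] <- all_reads
    truth[[d]] <- data.frame(donor = donor,
                             n_ref = sum(base_pass == snp$ref),
                             n_alt = sum(base_pass == snp$alt),
                             stringsAsFactors = FALSE)
  }
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Generate a complete synthetic study
#'
#' Orchestrates all generators into one coherent toy study: a genome with
#' open chromatin and TSS annotation; two cistromes with a planted
#' co-occupancy fraction; a DE table whose planted down-targets are the
#' genes nearest the co-occupied peaks; a planted risk SNP inside a
#' co-occupied peak pair (with, when a PWM is supplied, the motif consensus
#' written into the genome around the SNP so the ref allele fits the
#' consensus and the alt allele disrupts it); and heterozygous-donor allele
#' reads at that SNP.
#'
#' @param cfg A `"sim_config"`.
#' @param pwm Optional `"pwm"` whose consensus is embedded at the risk SNP.
#' @return A list with elements `world`, `peaks`, `annotated_a`, `de`,
#'   `genotypes`, `snp`, `ai`, and `truth` aggregating every generator's
#'   truth record.
#' @export
simulate_study <- function(cfg, pwm = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  world <- gen_genome(cfg)
  peaks <- gen_peaksets(cfg, world)
  ann_a <- nearest_tss(peaks$setA, world$tss)
  ov <- overlap_count(peaks$setA, peaks$setB)
  co_genes <- unique(ann_a$gene_id[ov$index])
  co_genes <- co_genes[!is.na(co_genes)]
  targets_down <- utils::head(sort(co_genes), cfg$de$n_down)
  detab <- gen_de_table(cfg, world$tss$gene_id, targets_down = targets_down)
  geno <- gen_genotypes(cfg)
  # plant the risk SNP inside the first co-occupied A/B peak pair
  set.seed(substream_seed(cfg$seed, "risk_snp"))
  i <- ov$index[1L]
  j <- which(GenomicRanges::countOverlaps(
    peaks$setB, peaks$setA[i], ignore.strand = TRUE) > 0L)[1L]
  lo <- max(start(peaks$setA)[i], start(peaks$setB)[j])
  hi <- min(end(peaks$setA)[i], end(peaks$setB)[j])
  pos <- (lo + hi) %/% 2L
  ctg <- as.character(seqnames(peaks$setA))[i]
  genome <- world$genome
  if (!is.null(pwm)) {
    w <- pwm$width
    consensus <- .DNA_BASES[apply(pwm$prob, 2L, which.max)]
    m_start <- pos - (w %/% 2L)
    at <- m_start:(m_start + w - 1L)
    seqs <- as.list(genome)
    seqs[[ctg]] <- Biostrings::replaceLetterAt(
      genome[[ctg]], at, Biostrings::DNAString(paste(consensus, collapse = "")))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- names(world$genome)
    snp_off <- pos - m_start + 1L
    ref <- consensus[snp_off]
    alt <- .DNA_BASES[which.min(pwm$prob[, snp_off])]
    if (alt == ref) alt <- setdiff(.DNA_BASES, ref)[1L]
  } else {
    ref <- as.character(Biostrings::subseq(genome[[ctg]], pos, pos))
    alt <- setdiff(.DNA_BASES, ref)[sample.int(3L, 1L)]
  }
  snp <- snp_record("rs_sim1", ctg, pos, ref, alt)
  world$genome <- genome
  ai <- gen_allelic_reads(cfg, snp)
  list(world = world, peaks = peaks, annotated_a = ann_a, de = detab$de,
       genotypes = geno$g, snp = snp, ai = ai,
       truth = list(peaks = peaks$truth, de = detab$truth,
                    ld = geno$truth, ai = ai$truth))
}
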