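# GWAS variant scan: tag-SNP expansion by LD, SNP-by-cistrome membership,
# and allele-aware PWM scoring of candidate regulatory variants.

#' Construct a genotype matrix
#'
#' @param dosages Samples x SNPs numeric matrix with entries in
#'   `{0, 1, 2, NA}` (alt-allele dosage).
#' @param snps SNP metadata (see [snp_record()]), one row per column of
#'   `dosages`, in column order.
#' @return An object of class `"genotype_matrix"` with elements `dosages`
#'   and `snps`; columns are named by SNP id.
#' @export
genotype_matrix <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  .need_cols(snps, c("id", "contig", "pos", "ref", "alt"), "SNP metadata")
  if (ncol(dosages) != nrow(snps))
    .stopf("dosage columns (%d) != SNP metadata rows (%d)",
           ncol(dosages), nrow(snps))
  if (any(!is.na(dosages) & !dosages %in% 0:2))
    .stopf("dosages must be in {0, 1, 2} or NA")
  colnames(dosages) <- snps$id
  structure(list(dosages = dosages, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

.snp_col <- function(g, i) {
  if (is.character(i)) {
    j <- match(i, g$snps$id)
    if (is.na(j)) .stopf("SNP %s absent from genotype matrix", i)
    j
  } else as.integer(i)
}

#' Pairwise linkage disequilibrium (r-squared) between two SNPs
#'
#' Squared Pearson correlation of alt-allele dosage vectors over the samples
#' non-missing at both SNPs (the genotypic r-squared for unphased data).
#' Symmetric in its arguments and invariant to flipping either SNP's
#' ref/alt encoding (dosage `0 <-> 2`).
#'
#' @param g A `"genotype_matrix"`.
#' @param i,j SNP column indices or ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g, i, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  x <- g$dosages[, .snp_col(g, i)]
  y <- g$dosages[, .snp_col(g, j)]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L)
    .stopf("fewer than 2 samples non-missing at both SNPs")
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    .stopf("monomorphic SNP over the shared non-missing samples")
  cor(x, y)^2
}

#' Expand tag SNPs by linkage disequilibrium
#'
#' For each tag, collects all SNPs within `window` bp on the same contig
#' whose dosage r-squared with the tag is strictly greater than
#' `r2_threshold`, and returns the deduplicated union of tags and LD mates —
#' the candidate causal set behind an association signal.
#'
#' @param tags Character vector of tag SNP ids (must all be present in `g`).
#' @param g A `"genotype_matrix"`.
#' @param r2_threshold Strict lower bound on r-squared (default 0.7).
#' @param window Search window around each tag in bp (default 1e6).
#' @return A SNP record data frame (rows of `g$snps`), sorted by contig and
#'   position, with a logical `is_tag` column.
#' @export
expand_tag_snps <- function(tags, g, r2_threshold = 0.7, window = 1e6) {
  stopifnot(inherits(g, "genotype_matrix"))
  miss <- setdiff(tags, g$snps$id)
  if (length(miss))
    .stopf("tag SNP(s) absent from genotype matrix: %s",
           paste(miss, collapse = ", "))
  keep <- logical(nrow(g$snps))
  for (tag in tags) {
    ti <- match(tag, g$snps$id)
    keep[ti] <- TRUE
    cand <- which(g$snps$contig == g$snps$contig[ti] &
                  abs(g$snps$pos - g$snps$pos[ti]) <= window)
    cand <- setdiff(cand, ti)
    for (ci in cand) {
      if (keep[ci]) next
      r2 <- tryCatch(ld_r2(g, ti, ci), error = function(e) NA_real_)
      if (!is.na(r2) && r2 > r2_threshold) keep[ci] <- TRUE
    }
  }
  out <- g$snps[keep, , drop = FALSE]
  out$is_tag <- out$id %in% tags
  out <- out[order(out$contig, out$pos, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect SNPs with one or more cistromes
#'
#' A SNP is inside a peak when `start <= pos <= end` (1-based closed; this
#' is the half-open BED test after coordinate conversion). The hit list
#' contains the SNPs inside every supplied cistrome — e.g. candidate causal
#' variants sitting in regions bound by both factors.
#'
#' @param snps A SNP record data frame.
#' @param cistromes A named list of `GRanges`.
#' @return A list: `membership`, a data frame with one logical column per
#'   cistrome plus `in_all`; and `hits`, the SNP ids inside all cistromes.
#' @export
intersect_snps_peaks <- function(snps, cistromes) {
  .need_cols(snps, c("id", "contig", "pos"), "SNP set")
  if (is.null(names(cistromes)) || any(!nzchar(names(cistromes))))
    .stopf("cistromes must be a named list")
  snp_gr <- GenomicRanges::GRanges(snps$contig,
                                   IRanges::IRanges(snps$pos, snps$pos))
  mem <- data.frame(id = snps$id, contig = snps$contig, pos = snps$pos,
                    stringsAsFactors = FALSE)
  for (nm in names(cistromes)) {
    mem[[nm]] <- suppressWarnings(
      GenomicRanges::countOverlaps(snp_gr, cistromes[[nm]],
                                   ignore.strand = TRUE)) > 0L
  }
  mem$in_all <- Reduce(`&`, mem[names(cistromes)])
  list(membership = mem, hits = mem$id[mem$in_all])
}

#' Score the effect of a SNP's alleles on a PWM match
#'
#' Substitutes each allele at the SNP position and scores every PWM window
#' covering the SNP, on both strands, with the log2-odds score
#' `sum(log2(P_pwm(base) / P_bg(base)))`. Two delta conventions are
#' offered: `"best_ref"` (default) evaluates both alleles on the single
#' window/strand that maximises the reference-allele score — measuring
#' disruption of the existing site — while `"max"` compares the best window
#' of each allele independently (exactly antisymmetric under ref/alt swap).
#'
#' @param pwm A `"pwm"` object.
#' @param genome A `DNAStringSet`; the base at the SNP must equal one of the
#'   two alleles.
#' @param snp A one-row SNP record.
#' @param flank Sequence context to extract on each side of the SNP; must be
#'   at least the PWM width.
#' @param mode `"best_ref"` or `"max"`.
#' @return An object of class `"allele_effect"`: `snp`, `ref_score`,
#'   `alt_score` (log2-odds bits), `delta` (`alt - ref`), `window_start`
#'   (contig coordinate of the scored window), `strand`, `mode`.
#' @export
scan_allele_effect <- function(pwm, genome, snp, flank = NULL,
                               mode = c("best_ref", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pwm, "pwm"), is(genome, "DNAStringSet"))
  .need_cols(snp, c("contig", "pos", "ref", "alt"), "SNP record")
  stopifnot(nrow(snp) == 1L)
  w <- pwm$width
  if (is.null(flank)) flank <- w
  if (flank < w) .stopf("flank (%d) must be >= PWM width (%d)", flank, w)
  ctg <- snp$contig
  if (!ctg %in% names(genome)) .stopf("contig %s absent from genome", ctg)
  L <- length(genome[[ctg]])
  pos <- as.integer(snp$pos)
  if (pos < 1L || pos > L) .stopf("SNP position out of bounds")
  base <- as.character(Biostrings::subseq(genome[[ctg]], pos, pos))
  if (!base %in% c(snp$ref, snp$alt))
    .stopf("genome base %s at %s:%d matches neither ref (%s) nor alt (%s)",
           base, ctg, pos, snp$ref, snp$alt)
  rs <- max(1L, pos - as.integer(flank))
  re <- min(L, pos + as.integer(flank))
  context <- as.character(Biostrings::subseq(genome[[ctg]], rs, re))
  at <- pos - rs + 1L                       # SNP offset within context
  sub_allele <- function(allele) {
    s <- context
    substr(s, at, at) <- allele
    s
  }
  # forward-strand window starts (within context) whose span covers the SNP
  starts <- seq.int(max(1L, at - w + 1L), min(at, nchar(context) - w + 1L))
  score_allele <- function(allele) {
    s <- sub_allele(allele)
    fwd <- .score_windows(pwm, s, "+")
    rev_ <- .score_windows(pwm, s, "-")
    rbind(fwd[starts], rev_[starts])        # 2 x n: strand x window
  }
  ref_sc <- score_allele(snp$ref)
  alt_sc <- score_allele(snp$alt)
  pick <- function(m) {
    k <- which.max(m)                       # column-major: strand fastest
    c(strand = (k - 1L) %% 2L + 1L, win = (k - 1L) %/% 2L + 1L)
  }
  if (mode == "best_ref") {
    p <- pick(ref_sc)
    ref_score <- ref_sc[p["strand"], p["win"]]
    alt_score <- alt_sc[p["strand"], p["win"]]
  } else {
    p <- pick(ref_sc)
    ref_score <- max(ref_sc)
    alt_score <- max(alt_sc)
  }
  structure(list(snp = snp, ref_score = unname(ref_score),
                 alt_score = unname(alt_score),
                 delta = unname(alt_score - ref_score),
                 window_start = rs + starts[p["win"]] - 1L,
                 strand = c("+", "-")[p["strand"]], mode = mode),
            class = "allele_effect")
}

#' @export
print.allele_effect <- function(x, ...) {
  cat(sprintf("Allele effect at %s (%s:%d %s>%s)\n", x$snp$id, x$snp$contig,
              x$snp$pos, x$snp$ref, x$snp$alt))
  cat(sprintf("  ref score: %.2f bits   alt score: %.2f bits\n",
              x$ref_score, x$alt_score))
  cat(sprintf("  delta (alt - ref): %.2f bits [%s, window %d, strand %s]\n",
              x$delta, x$mode, x$window_start, x$strand))
  invisible(x)
}
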