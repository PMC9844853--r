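#' @import Biostrings
NULL

# Genomes are Biostrings::DNAStringSet objects (alphabet A/C/G/T/N), one
# element per contig. I/O goes through Biostrings' FASTA reader/writer.

#' Read a genome from FASTA
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet], names taken from the FASTA headers
#'   (first whitespace-separated token).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (any(width(g) == 0L)) .stopf("empty contig in %s", path)
  g
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path; sequence lines are wrapped at 60 columns.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' GC content of genomic intervals
#'
#' Computes (G + C) / (A + C + G + T) per interval. N bases carry no
#' composition information and are excluded from both numerator and
#' denominator; an interval consisting entirely of N returns `NA`.
#'
#' @param genome A `DNAStringSet`.
#' @param intervals A `GRanges` (1-based closed, as produced by
#'   [read_intervals()]).
#' @return Numeric vector in `[0, 1]` (or `NA`), one value per interval.
#' @export
gc_content <- function(genome, intervals) {
  stopifnot(is(genome, "DNAStringSet"), is(intervals, "GRanges"))
  contig <- as.character(seqnames(intervals))
  miss <- setdiff(unique(contig), names(genome))
  if (length(miss))
    .stopf("contig(s) absent from genome: %s", paste(miss, collapse = ", "))
  out <- numeric(length(intervals))
  for (ctg in unique(contig)) {
    sel <- which(contig == ctg)
    L <- length(genome[[ctg]])
    s <- start(intervals)[sel]; e <- end(intervals)[sel]
    if (any(s < 1L | e > L))
      .stopf("interval out of bounds on contig %s (length %d)", ctg, L)
    v <- Biostrings::Views(genome[[ctg]], start = s, end = e)
    lf <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    denom <- rowSums(lf)
    out[sel] <- ifelse(denom == 0, NA_real_, (lf[, "G"] + lf[, "C"]) / denom)
  }
  out
}

#' Mask a SNP base with N
#'
#' Replaces the base at a SNP position with `N`, returning a modified copy of
#' the genome (the input is untouched). Masking the reference base before
#' re-aligning reads is the standard guard against reference-allele mapping
#' bias in allelic-imbalance analyses.
#'
#' @param genome A `DNAStringSet`.
#' @param snp A one-row SNP record (see [snp_record()]): columns `contig`,
#'   `pos` (1-based), `ref`, `alt`.
#' @return A new `DNAStringSet`, identical except for the masked position.
#' @export
mask_base <- function(genome, snp) {
  stopifnot(is(genome, "DNAStringSet"))
  .need_cols(snp, c("contig", "pos", "ref", "alt"), "SNP record")
  stopifnot(nrow(snp) == 1L)
  ctg <- snp$contig
  if (!ctg %in% names(genome)) .stopf("contig %s absent from genome", ctg)
  pos <- as.integer(snp$pos)
  if (pos < 1L || pos > length(genome[[ctg]]))
    .stopf("SNP position %d out of bounds on contig %s", pos, ctg)
  base <- as.character(Biostrings::subseq(genome[[ctg]], pos, pos))
  if (!base %in% c(snp$ref, snp$alt, "N"))
    .stopf("genome base %s at %s:%d matches neither ref (%s) nor alt (%s)",
           base, ctg, pos, snp$ref, snp$alt)
  seqs <- as.list(genome)
  seqs[[ctg]] <- Biostrings::replaceLetterAt(genome[[ctg]], pos,
                                             Biostrings::DNAString("N"))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(genome)
  out
}
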