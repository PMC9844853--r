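#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

# Interval sets are plain GRanges (1-based, closed, the Bioconductor
# convention). BED input/output is converted at the boundary: BED is 0-based
# half-open, so a BED record (start, end) becomes GRanges (start + 1, end).
# An optional `summit` metadata column carries the peak summit as a 0-based
# offset from the interval start, the convention of MACS-style peak callers.

.parse_strand <- function(x) {
  x[is.na(x) | x == "."] <- "*"
  if (!all(x %in% c("+", "-", "*")))
    .stopf("invalid strand value(s): %s",
           paste(unique(setdiff(x, c("+", "-", "*"))), collapse = ", "))
  x
}

#' Read a set of genomic intervals
#'
#' Reads peak/region files into a [GenomicRanges::GRanges]. Two formats are
#' supported: `"bed"` (whitespace-separated, no header, 0-based half-open;
#' columns chrom, start, end, and optionally name, score, strand, summit) and
#' `"tsv"` (tab-separated with a header declaring at least
#' `contig`/`start`/`end`, taken as 1-based inclusive coordinates, plus
#' optional `name`, `score`, `strand`, `summit` columns).
#'
#' The `summit` column, when present, is a 0-based offset from the interval
#' start (peak-caller convention) and is carried unchanged by both formats.
#'
#' @param path Path to the file.
#' @param format `"bed"` or `"tsv"`.
#' @return A `GRanges`; optional columns appear in `mcols()`.
#' @seealso [write_intervals()] for the inverse operation.
#' @export
read_intervals <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "bed") .read_bed(path) else .read_interval_tsv(path)
}

.empty_granges <- function() GenomicRanges::GRanges()

.read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) return(.empty_granges())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    .stopf("malformed BED line %d: fewer than 3 fields", which(nf < 3L)[1L])
  ncol <- min(nf)
  get <- function(k) vapply(fields, `[[`, character(1), k)
  chrom <- get(1L)
  start0 <- suppressWarnings(as.numeric(get(2L)))
  end0 <- suppressWarnings(as.numeric(get(3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) .stopf("malformed BED line %d: non-numeric coordinates", bad[1L])
  bad <- which(start0 >= end0)
  if (length(bad))
    .stopf("malformed BED line %d: start >= end (%d >= %d)",
           bad[1L], start0[bad[1L]], end0[bad[1L]])
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  if (ncol >= 4L) {
    nm <- get(4L)
    if (!all(nm == ".")) S4Vectors::mcols(gr)$name <- nm
  }
  if (ncol >= 5L) {
    sc <- get(5L)
    if (!all(sc == ".")) {
      scn <- suppressWarnings(as.numeric(sc))
      scn[sc == "."] <- NA_real_
      S4Vectors::mcols(gr)$score <- scn
    }
  }
  if (ncol >= 6L) strand(gr) <- .parse_strand(get(6L))
  if (ncol >= 7L) {
    sm <- suppressWarnings(as.integer(get(7L)))
    bad <- which(!is.na(sm) & (sm < 0L | sm >= width(gr)))
    if (length(bad))
      .stopf("malformed BED line %d: summit offset outside interval", bad[1L])
    S4Vectors::mcols(gr)$summit <- sm
  }
  gr
}

.read_interval_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "")
  if (!nrow(df)) return(.empty_granges())
  .need_cols(df, c("contig", "start", "end"), "interval TSV")
  bad <- which(df$start > df$end | is.na(df$start) | is.na(df$end))
  if (length(bad))
    .stopf("malformed interval on data line %d: start > end or missing", bad[1L])
  gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end))
  if ("strand" %in% names(df)) strand(gr) <- .parse_strand(df$strand)
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  if ("score" %in% names(df)) S4Vectors::mcols(gr)$score <- df$score
  if ("summit" %in% names(df)) {
    sm <- as.integer(df$summit)
    bad <- which(!is.na(sm) & (sm < 0L | sm >= width(gr)))
    if (length(bad))
      .stopf("malformed interval on data line %d: summit offset outside interval",
             bad[1L])
    S4Vectors::mcols(gr)$summit <- sm
  }
  gr
}

#' Write a set of genomic intervals
#'
#' Inverse of [read_intervals()]: `"bed"` emits 0-based half-open records
#' (BED3 when the set carries no names/scores/strands/summits, BED6 or
#' BED6+summit otherwise); `"tsv"` emits 1-based inclusive coordinates with a
#' header. A set written and re-read through either format round-trips with
#' identical coordinates and optional columns.
#'
#' @param x A `GRanges`.
#' @param path Output path.
#' @param format `"bed"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(x, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(x, "GRanges"))
  mc <- S4Vectors::mcols(x)
  has_name <- "name" %in% names(mc)
  has_score <- "score" %in% names(mc)
  has_summit <- "summit" %in% names(mc)
  has_strand <- length(x) > 0 && any(as.character(strand(x)) != "*")
  if (format == "bed") {
    if (!length(x)) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    cols <- list(as.character(seqnames(x)),
                 format(start(x) - 1L, scientific = FALSE, trim = TRUE),
                 format(end(x), scientific = FALSE, trim = TRUE))
    if (has_name || has_score || has_strand || has_summit) {
      nm <- if (has_name) mc$name else rep(".", length(x))
      sc <- if (has_score) ifelse(is.na(mc$score), ".", as.character(mc$score))
            else rep(".", length(x))
      st <- as.character(strand(x))
      st[st == "*"] <- "."
      cols <- c(cols, list(nm, sc, st))
      if (has_summit) cols <- c(cols, list(as.character(mc$summit)))
    }
    writeLines(do.call(paste, c(cols, sep = "\t")), path)
  } else {
    df <- data.frame(contig = as.character(seqnames(x)),
                     start = start(x), end = end(x),
                     stringsAsFactors = FALSE)
    if (has_strand) df$strand <- as.character(strand(x))
    if (has_name) df$name <- mc$name
    if (has_score) df$score <- mc$score
    if (has_summit) df$summit <- mc$summit
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Count query intervals overlapping a reference set
#'
#' Asymmetric, query-side overlap: how many intervals of `a` share at least
#' `min_bp` bases with at least one interval of `b`. Each `a` interval is
#' counted at most once no matter how many `b` intervals it touches; strand is
#' ignored. This is the co-occupancy statistic used throughout the package
#' (e.g. the fraction of one cistrome's peaks also bound by a second factor).
#'
#' @param a Query `GRanges`.
#' @param b Reference `GRanges`.
#' @param min_bp Minimum shared bases (default 1).
#' @return A list with `count` (number of overlapping `a` intervals),
#'   `index` (their indices in `a`) and `hits` (the corresponding subset of
#'   `a`).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 200), c(100, 300)))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 60))
#' overlap_count(a, b)$count
#' @export
overlap_count <- function(a, b, min_bp = 1L) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  if (!is.numeric(min_bp) || length(min_bp) != 1L || min_bp < 1)
    .stopf("min_bp must be a single integer >= 1")
  # disjoint contig namespaces are a legitimate zero-overlap case, not a
  # user error: silence the Seqinfo merge warning
  n <- suppressWarnings(
    GenomicRanges::countOverlaps(a, b, minoverlap = as.integer(min_bp),
                                 ignore.strand = TRUE))
  idx <- which(n > 0L)
  list(count = length(idx), index = idx, hits = a[idx])
}

# anchor position used for TSS distances: summit when present, else midpoint
.peak_anchor <- function(x) {
  anchor <- (start(x) + end(x)) %/% 2L
  mc <- S4Vectors::mcols(x)
  if ("summit" %in% names(mc)) {
    sm <- mc$summit
    use <- !is.na(sm)
    anchor[use] <- start(x)[use] + sm[use]
  }
  anchor
}

#' Assign peaks to their nearest transcription start site
#'
#' For each peak, the anchor (summit when available, else midpoint) is
#' compared against every TSS on the same contig and the gene with the
#' smallest unsigned distance is returned. Equidistant genes are broken
#' deterministically by lexicographically smallest gene id. Peaks on a contig
#' with no TSS are flagged (`no_tss = TRUE`), never silently dropped.
#'
#' @param peaks A `GRanges` of peaks.
#' @param tss A TSS map data frame with columns `gene_id`, `contig`, `tss`
#'   (1-based position), and optionally `strand` (see [tss_map()]).
#' @return A data frame with one row per peak: `contig`, `start`, `end`,
#'   `anchor`, `gene_id`, `distance` (unsigned, base pairs), `no_tss`.
#' @export
nearest_tss <- function(peaks, tss) {
  stopifnot(is(peaks, "GRanges"))
  .need_cols(tss, c("gene_id", "contig", "tss"), "TSS map")
  n <- length(peaks)
  anchor <- .peak_anchor(peaks)
  contig <- as.character(seqnames(peaks))
  out <- data.frame(contig = contig, start = start(peaks), end = end(peaks),
                    anchor = anchor, gene_id = NA_character_,
                    distance = NA_real_, no_tss = TRUE,
                    stringsAsFactors = FALSE)
  for (ctg in unique(contig)) {
    sel <- which(contig == ctg)
    ct <- tss[tss$contig == ctg, , drop = FALSE]
    if (!nrow(ct)) next
    ct <- ct[order(ct$tss, ct$gene_id), , drop = FALSE]
    first <- !duplicated(ct$tss)
    upos <- ct$tss[first]          # unique TSS positions, ascending
    ugene <- ct$gene_id[first]     # smallest gene id at each position
    a <- anchor[sel]
    k <- findInterval(a, upos)
    nl <- length(upos)
    dl <- ifelse(k >= 1L, a - upos[pmax(k, 1L)], Inf)
    dr <- ifelse(k < nl, upos[pmin(k + 1L, nl)] - a, Inf)
    gl <- ugene[pmax(k, 1L)]
    gr_ <- ugene[pmin(k + 1L, nl)]
    take_left <- dl < dr | (dl == dr & gl <= gr_)
    out$gene_id[sel] <- ifelse(take_left, gl, gr_)
    out$distance[sel] <- pmin(dl, dr)
    out$no_tss[sel] <- FALSE
  }
  out
}

#' Resize peaks to a fixed window around their summit
#'
#' Optional width standardisation: each peak becomes summit +/- `w` (midpoint
#' when no summit is recorded), clipped to stay within `[1, contig length]`
#' when lengths are supplied. Raw peak widths are the default everywhere else
#' in the package.
#'
#' @param x A `GRanges`.
#' @param w Half-width in bp.
#' @param contig_lengths Optional named vector of contig lengths for clipping.
#' @return A `GRanges` of width `2 * w + 1` (before clipping), summit column
#'   updated to the new offset.
#' @export
resize_to_summit <- function(x, w = 100L, contig_lengths = NULL) {
  stopifnot(is(x, "GRanges"), w >= 0)
  anchor <- .peak_anchor(x)
  s <- pmax(1L, anchor - as.integer(w))
  e <- anchor + as.integer(w)
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[as.character(seqnames(x))]
    e <- pmin(e, as.integer(len))
  }
  out <- GenomicRanges::GRanges(seqnames(x), IRanges::IRanges(s, e),
                                strand = strand(x))
  S4Vectors::mcols(out) <- S4Vectors::mcols(x)
  S4Vectors::mcols(out)$summit <- anchor - s
  out
}
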