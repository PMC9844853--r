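# Covariate-matched permutation null for cistrome co-occupancy. Random
# region sets are (1) constrained to open chromatin, (2) matched exactly, at
# bin resolution, on the joint GC-content x distance-to-nearest-TSS profile
# of the template peak set, with lengths resampled from the template length
# distribution. The empirical p-value uses the +1 (Phipson-Smyth)
# correction.

#' Default GC and distance bin edges for profile matching
#'
#' GC is binned at width 0.05 over `[0, 1]`; distance to the nearest TSS in
#' log10-spaced bins from 1 bp to 10 Mbp plus an overflow bin. Matching is
#' exact at this bin resolution.
#' @name matching_bins
#' @export
default_gc_breaks <- function() seq(0, 1, by = 0.05)

#' @rdname matching_bins
#' @export
default_distance_breaks <- function() c(0, 10^seq(0, 7, length.out = 10), Inf)

# joint bin key; gc NA (all-N interval) gets the dedicated gc bin 0
.joint_bin <- function(gc, dist, gc_breaks, dist_breaks) {
  gcbin <- findInterval(gc, gc_breaks, rightmost.closed = TRUE)
  gcbin[is.na(gc)] <- 0L
  dbin <- findInterval(dist, dist_breaks)
  gcbin * 100L + dbin
}

#' Precompute the covariate context for matched-null sampling
#'
#' Builds the per-contig structures that make repeated matched sampling
#' cheap: cumulative GC/ACGT base counts (constant-time interval GC), sorted
#' TSS positions (log-time nearest-TSS distance), and the open-chromatin
#' table with cumulative widths (uniform sampling over open bases). Build it
#' once and pass it to [build_profile()], [sample_matched_set()] or
#' [permutation_overlap_test()] when running many tests against the same
#' genome.
#'
#' @param genome A `DNAStringSet`.
#' @param tss A TSS map data frame.
#' @param open_chromatin `GRanges` of the open-chromatin universe.
#' @return An object of class `"null_context"`.
#' @export
null_context <- function(genome, tss, open_chromatin) {
  stopifnot(is(genome, "DNAStringSet"), is(open_chromatin, "GRanges"))
  .need_cols(tss, c("contig", "tss"), "TSS map")
  contigs <- names(genome)
  gc_cum <- vector("list", length(contigs)); names(gc_cum) <- contigs
  acgt_cum <- gc_cum; tss_pos <- gc_cum
  for (ctg in contigs) {
    r <- as.integer(charToRaw(as.character(genome[[ctg]])))
    is_gc <- (r == 71L | r == 67L | r == 103L | r == 99L)      # G C g c
    is_acgt <- is_gc | r == 65L | r == 84L | r == 97L | r == 116L
    gc_cum[[ctg]] <- c(0L, cumsum(is_gc))
    acgt_cum[[ctg]] <- c(0L, cumsum(is_acgt))
    tss_pos[[ctg]] <- sort(tss$tss[tss$contig == ctg])
  }
  oc <- as.character(seqnames(open_chromatin))
  if (!all(oc %in% contigs)) .stopf("open-chromatin contig absent from genome")
  w <- width(open_chromatin)
  structure(list(contigs = contigs, gc_cum = gc_cum, acgt_cum = acgt_cum,
                 tss_pos = tss_pos,
                 open = list(contig = oc, start = start(open_chromatin),
                             end = end(open_chromatin)),
                 open_cum0 = c(0, cumsum(as.numeric(w))),
                 open_total = sum(as.numeric(w))),
            class = "null_context")
}

#' @export
print.null_context <- function(x, ...) {
  cat(sprintf("Matched-null context: %d contig(s), %d open interval(s) (%.3g bp)\n",
              length(x$contigs), length(x$open$start), x$open_total))
  invisible(x)
}

# vectorised interval GC over one contig's cumulative arrays
.ctx_gc <- function(ctx, ctg, s, e) {
  gcc <- ctx$gc_cum[[ctg]]; acc <- ctx$acgt_cum[[ctg]]
  L <- length(gcc) - 1L
  if (any(s < 1L | e > L)) .stopf("interval out of bounds on contig %s", ctg)
  denom <- acc[e + 1L] - acc[s]
  out <- (gcc[e + 1L] - gcc[s]) / denom
  out[denom == 0L] <- NA_real_
  out
}

# vectorised distance from anchors to the nearest TSS on one contig
.ctx_dist <- function(ctx, ctg, anchor) {
  p <- ctx$tss_pos[[ctg]]
  np <- length(p)
  if (!np) return(rep(Inf, length(anchor)))
  k <- findInterval(anchor, p)
  dl <- rep(Inf, length(anchor)); dr <- dl
  hasl <- k >= 1L
  dl[hasl] <- anchor[hasl] - p[k[hasl]]
  hasr <- k < np
  dr[hasr] <- p[k[hasr] + 1L] - anchor[hasr]
  pmin(dl, dr)
}

# gc + distance + joint bin for arbitrary intervals (splits by contig)
.ctx_bins <- function(ctx, contig, s, e, gc_breaks, dist_breaks) {
  gc <- numeric(length(s)); dist <- numeric(length(s))
  for (ctg in unique(contig)) {
    sel <- which(contig == ctg)
    gc[sel] <- .ctx_gc(ctx, ctg, s[sel], e[sel])
    dist[sel] <- .ctx_dist(ctx, ctg, (s[sel] + e[sel]) %/% 2L)
  }
  list(gc = gc, dist = dist,
       bin = .joint_bin(gc, dist, gc_breaks, dist_breaks))
}

#' Build the joint GC x distance matching profile of a template peak set
#'
#' Assigns every template interval to exactly one joint (GC bin, distance
#' bin) cell; intervals whose GC is undefined (all N) go to a dedicated bin.
#' Distance is measured from the peak anchor (summit when present, else
#' midpoint) to the nearest TSS. The profile also records the template
#' length distribution, from which null sets resample their lengths.
#'
#' @param template Template `GRanges` (must be nonempty).
#' @param genome A `DNAStringSet` covering all template contigs.
#' @param tss A TSS map data frame.
#' @param gc_breaks,dist_breaks Bin edges (see [default_gc_breaks()]).
#' @param context Optional precomputed [null_context()] (then `genome` and
#'   `tss` may be missing).
#' @return An object of class `"matching_profile"`: `n`, `counts` (named
#'   integer vector of joint-bin counts summing to `n`), `lengths`,
#'   `gc_breaks`, `dist_breaks`, plus per-interval `gc`, `dist`, `bin`.
#' @export
build_profile <- function(template, genome, tss,
                          gc_breaks = default_gc_breaks(),
                          dist_breaks = default_distance_breaks(),
                          context = NULL) {
  stopifnot(is(template, "GRanges"))
  if (!length(template)) .stopf("template set is empty")
  if (is.unsorted(gc_breaks, strictly = TRUE) ||
      is.unsorted(dist_breaks, strictly = TRUE))
    .stopf("bin edges must be strictly increasing")
  if (is.null(context)) {
    context <- null_context(genome, tss,
                            GenomicRanges::GRanges(names(genome)[1L],
                                                   IRanges::IRanges(1, 1)))
  }
  contig <- as.character(seqnames(template))
  s <- start(template); e <- end(template)
  gc <- numeric(length(s)); dist <- numeric(length(s))
  anchor <- .peak_anchor(template)
  for (ctg in unique(contig)) {
    sel <- which(contig == ctg)
    gc[sel] <- .ctx_gc(context, ctg, s[sel], e[sel])
    dist[sel] <- .ctx_dist(context, ctg, anchor[sel])
  }
  bin <- .joint_bin(gc, dist, gc_breaks, dist_breaks)
  tab <- table(bin)
  counts <- setNames(as.integer(tab), names(tab))
  structure(list(n = length(template), counts = counts,
                 lengths = width(template),
                 gc_breaks = gc_breaks, dist_breaks = dist_breaks,
                 gc = gc, dist = dist, bin = bin),
            class = "matching_profile")
}

#' @export
print.matching_profile <- function(x, ...) {
  cat(sprintf("Matching profile: %d intervals over %d occupied joint bins\n",
              x$n, length(x$counts)))
  cat(sprintf("  GC bins: width %.3g; distance bins: %d edges\n",
              diff(x$gc_breaks)[1L], length(x$dist_breaks)))
  invisible(x)
}

# core sampler (no reseeding): rejection-sample uniform open-chromatin
# positions until every joint bin quota is filled exactly; returns plain
# vectors to keep S4 construction out of the permutation loop
.sample_matched <- function(profile, ctx, max_rejections = 10000) {
  quota <- profile$counts
  quota_bins <- as.integer(names(quota))
  n <- profile$n
  remaining <- unname(quota)
  acc_contig <- character(0); acc_s <- integer(0); acc_e <- integer(0)
  tries <- 0
  max_tries <- max_rejections * n
  op <- ctx$open
  n_open <- length(op$start)
  n_lens <- length(profile$lengths)
  stall <- 0L   # doubles the batch when draws stop landing in open bins
  while (sum(remaining) > 0L) {
    left <- sum(remaining)
    m <- min(50000L, max(256L, 4L * left) * 2L^min(stall, 8L))
    tries <- tries + m
    len <- profile$lengths[sample.int(n_lens, m, replace = TRUE)]
    u <- runif(m) * ctx$open_total
    j <- findInterval(u, ctx$open_cum0, rightmost.closed = TRUE)
    j[j < 1L] <- 1L; j[j > n_open] <- n_open
    s <- op$start[j] + as.integer(u - ctx$open_cum0[j])
    e <- s + len - 1L
    keep <- e <= op$end[j]
    if (!any(keep)) {
      if (tries > max_tries) break
      next
    }
    s <- s[keep]; e <- e[keep]; contig <- op$contig[j[keep]]
    b <- .ctx_bins(ctx, contig, s, e, profile$gc_breaks, profile$dist_breaks)
    gi <- match(b$bin, quota_bins)          # quota group per candidate
    valid <- which(!is.na(gi))
    before <- sum(remaining)
    if (length(valid)) {
      o <- valid[order(gi[valid])]
      rnk <- sequence(rle(gi[o])$lengths)   # rank within each quota group
      take <- o[rnk <= remaining[gi[o]]]
      if (length(take)) {
        acc_contig <- c(acc_contig, contig[take])
        acc_s <- c(acc_s, s[take])
        acc_e <- c(acc_e, e[take])
        remaining <- remaining - tabulate(gi[take], nbins = length(remaining))
      }
    }
    stall <- if (sum(remaining) < before) 0L else stall + 1L
    if (sum(remaining) > 0L && tries > max_tries) break
  }
  if (sum(remaining) > 0L) {
    worst <- which.max(remaining)
    .stopf(paste0("could not fill matching bin %s (%d of %d still unfilled ",
                  "after ~%d draws); use coarser bins or a larger ",
                  "open-chromatin universe"),
           names(quota)[worst], remaining[worst], quota[worst], tries)
  }
  list(contig = acc_contig, start = acc_s, end = acc_e)
}

#' Sample one random region set matched to a template profile
#'
#' Draws a set with the template's cardinality in which every interval lies
#' entirely within open chromatin, lengths are resampled (with replacement)
#' from the template's length distribution, and the joint GC x distance bin
#' counts equal the template profile's exactly. Sampling is by rejection:
#' positions are drawn uniformly over open-chromatin bases and accepted
#' while their joint bin still has unfilled quota.
#'
#' @param profile A `"matching_profile"` from [build_profile()].
#' @param open_chromatin `GRanges` of the open-chromatin universe.
#' @param genome,tss As in [build_profile()].
#' @param seed Integer seed; identical inputs and seed give a bit-identical
#'   set.
#' @param max_rejections Attempt budget per template interval before giving
#'   up on an unfillable bin (default 10000).
#' @param context Optional precomputed [null_context()] (then
#'   `open_chromatin`, `genome` and `tss` may be missing).
#' @return A `GRanges` of sampled intervals.
#' @export
sample_matched_set <- function(profile, open_chromatin, genome, tss, seed,
                               max_rejections = 10000, context = NULL) {
  stopifnot(inherits(profile, "matching_profile"))
  if (missing(seed)) .stopf("seed must be supplied")
  if (is.null(context)) context <- null_context(genome, tss, open_chromatin)
  set.seed(as.integer(seed))
  s <- .sample_matched(profile, context, max_rejections = max_rejections)
  GenomicRanges::GRanges(s$contig, IRanges::IRanges(s$start, s$end))
}

# fast query-side overlap counter against a fixed reference set:
# precompute per-contig sorted starts and running max of ends
.overlap_counter <- function(b) {
  contig <- as.character(seqnames(b))
  idx <- split(seq_along(b), contig)
  lapply(idx, function(i) {
    s <- start(b)[i]; e <- end(b)[i]
    o <- order(s)
    list(starts = s[o], maxend = cummax(e[o]))
  })
}

.count_query_overlaps <- function(counter, contig, s, e) {
  hits <- logical(length(s))
  for (ctg in unique(contig)) {
    cc <- counter[[ctg]]
    if (is.null(cc)) next
    sel <- which(contig == ctg)
    k <- findInterval(e[sel], cc$starts)   # reference starts <= query end
    hits[sel] <- k >= 1L & cc$maxend[pmax(k, 1L)] >= s[sel]
  }
  sum(hits)
}

#' Covariate-matched permutation test of cistrome co-occupancy
#'
#' Tests whether the observed query-side overlap between two peak sets
#' exceeds what is expected for random region sets that fall within open
#' chromatin and share `setA`'s joint GC-content and distance-to-TSS
#' profile. For each permutation a matched random set replaces `setA` and
#' its overlap with the genuine `setB` is recorded; the one-sided empirical
#' p-value is `(#{null >= observed} + 1) / (n_perm + 1)`, so its floor at
#' `n_perm` permutations is `1 / (n_perm + 1)`.
#'
#' @param setA Query `GRanges` (the set being randomised; conventionally the
#'   smaller cistrome).
#' @param setB Reference `GRanges` (held fixed).
#' @param open_chromatin Open-chromatin `GRanges` universe for null sets.
#' @param genome,tss Genome and TSS map for the matching covariates.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (mandatory; the result is reproducible).
#' @param min_bp Minimum overlap in bp (default 1).
#' @param gc_breaks,dist_breaks Matching bin edges.
#' @param max_rejections Passed to the sampler.
#' @param context Optional precomputed [null_context()]; when supplied,
#'   `open_chromatin`, `genome` and `tss` may be missing.
#' @return An object of class `"permutation_result"`: `observed`,
#'   `null_draws` (length `n_perm`), `null_mean`, `empirical_p`, `n_perm`,
#'   `seed`.
#' @export
permutation_overlap_test <- function(setA, setB, open_chromatin, genome, tss,
                                     n_perm = 1000, seed, min_bp = 1L,
                                     gc_breaks = default_gc_breaks(),
                                     dist_breaks = default_distance_breaks(),
                                     max_rejections = 10000,
                                     context = NULL) {
  stopifnot(is(setA, "GRanges"), is(setB, "GRanges"))
  if (missing(seed)) .stopf("seed must be supplied")
  if (n_perm < 1) .stopf("n_perm must be >= 1")
  if (is.null(context)) context <- null_context(genome, tss, open_chromatin)
  observed <- overlap_count(setA, setB, min_bp = min_bp)$count
  profile <- build_profile(setA, gc_breaks = gc_breaks,
                           dist_breaks = dist_breaks, context = context)
  counter <- .overlap_counter(setB)
  use_fast <- min_bp == 1L
  set.seed(as.integer(seed))
  null_draws <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    s <- .sample_matched(profile, context, max_rejections = max_rejections)
    null_draws[i] <- if (use_fast) {
      .count_query_overlaps(counter, s$contig, s$start, s$end)
    } else {
      overlap_count(GenomicRanges::GRanges(s$contig,
                                           IRanges::IRanges(s$start, s$end)),
                    setB, min_bp = min_bp)$count
    }
  }
  structure(list(observed = observed, null_draws = null_draws,
                 null_mean = mean(null_draws),
                 empirical_p = (sum(null_draws >= observed) + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Matched-null permutation overlap test\n")
  cat(sprintf("  observed overlap: %d\n", x$observed))
  cat(sprintf("  null mean:        %.1f (%d permutations)\n",
              x$null_mean, x$n_perm))
  cat(sprintf("  empirical p:      %.4g%s\n", x$empirical_p,
              if (x$empirical_p <= 1 / (x$n_perm + 1))
                sprintf(" (floor at %d permutations)", x$n_perm) else ""))
  invisible(x)
}
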