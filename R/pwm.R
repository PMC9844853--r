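# Position weight matrices with an explicit background model, scored as
# log2 odds. Stored as a small S3 object: a 4 x W probability matrix (rows
# A, C, G, T), the background distribution, and the pseudocount used at
# normalisation time.

.DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Counts (or frequencies) are normalised column-wise to probabilities with a
#' background-weighted pseudocount: column entries become
#' `(c_b + pseudocount * 4 * bg_b) / (sum(c) + 4 * pseudocount)`, so with a
#' uniform background each cell gains exactly `pseudocount` pseudo-counts
#' (`pseudocount = 1` reproduces the textbook `(c + 1) / (sum + 4)` rule).
#'
#' @param counts A 4 x W numeric matrix of nonnegative counts or frequencies,
#'   rows in A, C, G, T order (rownames, if present, are checked).
#' @param background Length-4 base probabilities (default uniform).
#' @param pseudocount Nonnegative pseudocount (default 0.8, split by
#'   background).
#' @param name Optional motif label.
#' @return An object of class `"pwm"` with elements `prob` (4 x W
#'   probability matrix), `background`, `pseudocount`, `name`, `width`.
#' @export
pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.8,
                name = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) .stopf("PWM must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts)) && !identical(toupper(rownames(counts)), .DNA_BASES))
    .stopf("PWM rownames must be A, C, G, T in order")
  if (any(counts < 0)) .stopf("negative PWM entries")
  if (any(is.na(counts))) .stopf("missing PWM entries")
  if (pseudocount < 0) .stopf("pseudocount must be >= 0")
  if (length(background) != 4L || any(background < 0))
    .stopf("background must be 4 nonnegative probabilities")
  background <- background / sum(background)
  colsum <- colSums(counts)
  if (any(colsum == 0) && pseudocount == 0)
    .stopf("all-zero PWM column with zero pseudocount")
  prob <- sweep(counts, 2L, colsum + 4 * pseudocount, "/") +
    (pseudocount * 4 * background) / rep(colsum + 4 * pseudocount, each = 4L)
  dimnames(prob) <- list(.DNA_BASES, NULL)
  structure(list(prob = prob, background = background,
                 pseudocount = pseudocount, name = name,
                 width = ncol(prob)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM%s: width %d, pseudocount %g\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$width, x$pseudocount))
  print(round(x$prob, 3))
  invisible(x)
}

#' Read a PWM from JASPAR-style matrix text
#'
#' Accepts the plain-text JASPAR matrix format: an optional `>` header line
#' followed by four rows (A, C, G, T) of equal length, with or without the
#' base label and square brackets, e.g. `A [ 12  3  0 ]`.
#'
#' @param path File path.
#' @inheritParams pwm
#' @return A `"pwm"` object; the motif name is taken from the header line
#'   when present.
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- NULL
  if (length(lines) && startsWith(lines[1L], ">")) {
    name <- trimws(sub("^>", "", lines[1L]))
    lines <- lines[-1L]
  }
  if (length(lines) != 4L)
    .stopf("JASPAR matrix must have exactly 4 data rows, found %d", length(lines))
  rows <- lapply(seq_len(4L), function(i) {
    ln <- gsub("[][]", " ", lines[i])
    ln <- sub(sprintf("^\\s*%s\\s+", .DNA_BASES[i]), " ", ln)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
    if (any(is.na(vals))) .stopf("non-numeric entry in PWM row %s", .DNA_BASES[i])
    vals
  })
  if (length(unique(lengths(rows))) != 1L)
    .stopf("PWM rows have unequal lengths: %s", paste(lengths(rows), collapse = ", "))
  pwm(do.call(rbind, rows), background = background, pseudocount = pseudocount,
      name = name)
}

# log2-odds score matrix: 4 x W of log2(P / bg)
.pwm_logodds <- function(p) log2(p$prob / p$background)

# score every window of pwm width in `seq` (character scalar) on the given
# strand; windows containing non-ACGT bases score -Inf
.score_windows <- function(p, seq, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  ch <- strsplit(seq, "")[[1L]]
  idx <- match(ch, .DNA_BASES)
  w <- p$width
  n <- length(idx) - w + 1L
  if (n < 1L) return(numeric(0))
  lo <- .pwm_logodds(p)
  sc <- numeric(n)
  ok <- rep(TRUE, n)
  for (i in seq_len(w)) {
    b <- idx[i:(i + n - 1L)]
    bad <- is.na(b)
    ok <- ok & !bad
    b[bad] <- 1L
    sc <- sc + lo[cbind(b, i)]
  }
  sc[!ok] <- -Inf
  if (strand == "-") rev(sc) else sc   # re-index to forward-strand starts
}
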