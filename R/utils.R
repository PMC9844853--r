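#' @importFrom methods is
#' @importFrom stats dbinom pbinom pchisq rbinom rnorm runif
#'   setNames wilcox.test
#' @importFrom utils read.table write.table
NULL

# stop() with sprintf formatting; call. = FALSE keeps messages clean
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a per-stage random seed from a master seed
#'
#' All generators in the package draw their randomness from a single master
#' seed, split by stage name, so that adding or reordering a downstream stage
#' never perturbs the random stream of an earlier one.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label (e.g. `"genome"`, `"peaks"`).
#' @return An integer seed in `[0, 2^31)`, a deterministic function of
#'   `(seed, stage)`.
#' @examples
#' substream_seed(1L, "genome")
#' substream_seed(1L, "peaks")
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + h * 30269) %% 2147483629)
}

# checks a data.frame has the given columns
.need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s is missing required column(s): %s", what,
           paste(miss, collapse = ", "))
  invisible(TRUE)
}
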