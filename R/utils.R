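#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom rpois rnbinom rbeta runif rexp cor optim
#'   optimize loess predict p.adjust pnorm dbinom qlogis plogis lm coef
#'   ks.test fisher.test phyper complete.cases setNames
#' @importFrom utils head read.delim write.table
NULL

# Single entry point for seeded randomness: every simulator routes its draws
# through here so no global RNG state leaks in or out.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed) || !is.numeric(seed)) {
    stop("a numeric 'seed' is required; seedless simulation is not supported",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assert_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Convert a 1-based variant position to its 0-based interval offset
#'
#' BED intervals are 0-based half-open; variant tables follow the VCF
#' convention of 1-based positions. All interval intersections in the package
#' funnel through this one conversion: a 1-based position `p` hits interval
#' `[s, e)` iff `s <= p - 1 < e`.
#'
#' @param pos integer vector of 1-based positions.
#' @return 0-based offsets (`pos - 1`).
#' @export
pos_to_offset <- function(pos) as.integer(pos) - 1L

validate_intervals <- function(start, end) {
  if (any(is.na(start)) || any(is.na(end)) || any(end <= start)) {
    bad <- which(is.na(start) | is.na(end) | end <= start)
    stop(sprintf("malformed interval(s) with end <= start at row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# GRanges from 0-based half-open intervals (IRanges is 1-based closed).
granges_from_bed <- function(chrom, start, end, id = NULL) {
  validate_intervals(start, end)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
  if (!is.null(id)) names(gr) <- id
  gr
}

# GRanges point positions from 1-based variant coordinates.
granges_from_positions <- function(chrom, pos) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L)
  )
}
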