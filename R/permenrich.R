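# Permutation test for enrichment of risk variants within an element set,
# with the exact hypergeometric tail as a small-universe oracle.

#' Permutation test of risk-SNP overlap with an element set
#'
#' The observed statistic is the number of risk SNPs whose position falls
#' inside an element. Each permutation draws `|risk_snps|` SNPs without
#' replacement from the universe -- within matched MAF bins when a `maf_bin`
#' column is provided -- and recounts the overlap. The empirical p-value
#' uses the standard add-one pseudocount,
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`, so p is never 0.
#'
#' @param risk_snps character vector of risk SNP ids (subset of the
#'   universe).
#' @param universe data.frame with snp, chrom, pos (1-based), and optionally
#'   maf_bin for frequency-matched draws.
#' @param element_set data.frame of intervals with id, chrom, start, end
#'   (0-based half-open).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; required.
#' @return object of class `OverlapTest`: list with observed, n_perm,
#'   perm_overlaps, p, scheme, seed.
#' @export
permutation_overlap_test <- function(risk_snps, universe, element_set,
                                     n_perm = 10000L, seed) {
  n_perm <- assert_count(n_perm, "n_perm", min = 100L)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (!all(risk_snps %in% universe$snp)) {
    stop("risk_snps must be a subset of the universe", call. = FALSE)
  }
  n_draw <- length(risk_snps)
  if (n_draw > nrow(universe)) {
    stop("more risk SNPs than universe SNPs", call. = FALSE)
  }
  hits <- intersect_variants_elements(universe, element_set)
  in_element <- lengths(hits) > 0
  names(in_element) <- universe$snp
  observed <- sum(in_element[risk_snps])

  matched <- !is.null(universe$maf_bin)
  if (matched) {
    bin_of <- setNames(universe$maf_bin, universe$snp)
    need <- table(bin_of[risk_snps])
    avail <- table(universe$maf_bin)
    short <- names(need)[need > avail[names(need)]]
    if (length(short) > 0) {
      stop(sprintf("MAF bin(s) smaller than required draw: %s",
                   paste(short, collapse = ", ")), call. = FALSE)
    }
    bin_idx <- split(seq_len(nrow(universe)), universe$maf_bin)
  }

  perm_overlaps <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      draw <- if (matched) {
        unlist(lapply(names(need), function(b) {
          idx <- bin_idx[[b]]
          idx[sample.int(length(idx), need[[b]])]
        }), use.names = FALSE)
      } else {
        sample.int(nrow(universe), n_draw)
      }
      sum(in_element[draw])
    }, numeric(1))
  })

  out <- list(
    observed = observed,
    n_perm = n_perm,
    perm_overlaps = perm_overlaps,
    p = (1 + sum(perm_overlaps >= observed)) / (1 + n_perm),
    scheme = if (matched) "maf_matched_snp_draw" else "unmatched_snp_draw",
    n_draws = n_draw,
    n_overlapping_universe = sum(in_element),
    universe_size = nrow(universe),
    seed = seed
  )
  class(out) <- "OverlapTest"
  out
}

#' @export
print.OverlapTest <- function(x, ...) {
  cat(sprintf(
    "OverlapTest: observed %d/%d in elements; p = %.4g (%d permutations, %s)\n",
    x$observed, x$n_draws, x$p, x$n_perm, x$scheme))
  invisible(x)
}

#' Exact hypergeometric overlap p-value
#'
#' The upper tail `P(X >= observed)` when drawing `n_draws` SNPs without
#' replacement from a universe of `universe_size` SNPs of which
#' `n_overlapping` lie in elements; the exact counterpart (and oracle) of
#' the unmatched permutation test, evaluated in log space.
#'
#' @param universe_size,n_overlapping,n_draws,observed counts.
#' @return exact p-value.
#' @export
exact_overlap_p <- function(universe_size, n_overlapping, n_draws, observed) {
  if (n_overlapping > universe_size || n_draws > universe_size ||
      observed > min(n_draws, n_overlapping) || observed < 0) {
    stop("inconsistent counts", call. = FALSE)
  }
  if (observed == 0) return(1)
  phyper(observed - 1, n_overlapping, universe_size - n_overlapping,
         n_draws, lower.tail = FALSE)
}
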