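# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Brute-force all-pairs variant/interval overlap (1-based positions vs
# 0-based half-open intervals).
brute_force_overlap <- function(variants, elements) {
  out <- setNames(vector("list", nrow(variants)), variants$snp)
  for (i in seq_len(nrow(variants))) {
    hit <- elements$chrom == variants$chrom[i] &
      elements$start <= variants$pos[i] - 1 &
      variants$pos[i] - 1 < elements$end
    out[[i]] <- sort(elements$id[hit])
  }
  out
}

# Two-sided minimum-likelihood exact binomial p by direct enumeration.
binom_twosided_oracle <- function(k, n, p0) {
  pmf <- dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# Symmetric-distance two-sided binomial p; an independent construction
# valid at p0 = 0.5 where the pmf is symmetric and unimodal.
binom_symmetric_oracle <- function(k, n) {
  d <- abs(k - n / 2)
  sum(dbinom(0:n, n, 0.5)[abs(0:n - n / 2) >= d - 1e-9])
}

# Textbook two-sample KS: ECDF sup distance and asymptotic p via the
# Kolmogorov series.
ks_oracle <- function(x, y) {
  all_v <- sort(unique(c(x, y)))
  Fx <- vapply(all_v, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(all_v, function(v) mean(y <= v), numeric(1))
  D <- max(abs(Fx - Fy))
  t <- sqrt(length(x) * length(y) / (length(x) + length(y))) * D
  j <- 1:200
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  list(D = D, p = max(min(p, 1), 0))
}

# Rank-based AUROC of scores for binary labels.
auroc <- function(score, label) {
  r <- rank(score)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Shared small LD panel for cross-file reuse.
small_panel <- function(seed = 42L) {
  simulate_haplotype_panel(
    n_individuals = 100L, n_blocks = 2L, snps_per_block = 25L,
    n_founders_per_block = 4L, mutation_rate = 0.05, seed = seed
  )
}
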