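# Allele-specific chromatin accessibility: genotype inference from allele
# read depths, heterozygote pooling, a global beta-binomial null fit per
# dataset, per-SNP exact imbalance tests, and cross-dataset concordance.

#' Infer a genotype from allele read counts
#'
#' Individuals with fewer than `min_depth` reads at a SNP are excluded;
#' otherwise an individual is heterozygous iff both alleles were observed
#' at least once, and homozygous for the single observed allele otherwise.
#'
#' @param ref_reads,alt_reads non-negative read counts (vectorized).
#' @param min_depth minimum total reads to genotype (default 5).
#' @return character vector in {"hom_ref", "het", "hom_alt", "excluded"}.
#' @export
infer_genotype <- function(ref_reads, alt_reads, min_depth = 5L) {
  if (any(ref_reads < 0) || any(alt_reads < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  total <- ref_reads + alt_reads
  ifelse(total < min_depth, "excluded",
         ifelse(ref_reads >= 1 & alt_reads >= 1, "het",
                ifelse(alt_reads == 0, "hom_ref", "hom_alt")))
}

#' Pool heterozygote reads per SNP
#'
#' Sums reference and total reads across all inferred heterozygotes for each
#' SNP; homozygous and excluded individuals contribute nothing, and SNPs
#' with no heterozygotes are dropped.
#'
#' @param table data.frame with snp, individual, ref_reads, alt_reads.
#' @param min_depth genotyping depth floor passed to [infer_genotype()].
#' @return data.frame: snp, k (pooled ref reads), n (pooled total reads),
#'   n_hets, ref_fraction.
#' @export
pool_het_counts <- function(table, min_depth = 5L) {
  geno <- infer_genotype(table$ref_reads, table$alt_reads, min_depth)
  het <- table[geno == "het", , drop = FALSE]
  if (nrow(het) == 0L) {
    return(data.frame(snp = character(0), k = integer(0), n = integer(0),
                      n_hets = integer(0), ref_fraction = numeric(0)))
  }
  k <- tapply(het$ref_reads, het$snp, sum)
  n <- tapply(het$ref_reads + het$alt_reads, het$snp, sum)
  n_hets <- tapply(rep(1L, nrow(het)), het$snp, sum)
  out <- data.frame(
    snp = names(k),
    k = as.integer(k), n = as.integer(n), n_hets = as.integer(n_hets),
    ref_fraction = as.numeric(k / n),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$snp), , drop = FALSE]
}

#' Beta-binomial probability mass function
#'
#' Parameterized by mean `mu` and overdispersion `rho`; for `rho > 0`,
#' `alpha = mu (1 - rho) / rho` and `beta = (1 - mu) (1 - rho) / rho`, and
#' the variance is `n mu (1 - mu) (1 + (n - 1) rho)`. `rho = 0` (or below
#' 1e-10) degenerates to the binomial.
#'
#' @param k,n successes and trials.
#' @param mu mean success probability in (0, 1).
#' @param rho overdispersion in [0, 1).
#' @param log return log-probabilities?
#' @return (log-)probabilities.
#' @export
dbetabinom <- function(k, n, mu, rho, log = FALSE) {
  if (rho < 1e-10) {
    return(dbinom(k, n, mu, log = log))
  }
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lp <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  if (log) lp else exp(lp)
}

#' Draw beta-binomial random variates
#'
#' Mean/overdispersion parameterization matching [dbetabinom()]; used to
#' exercise the fitter and test against data drawn from its own model.
#'
#' @param n_draws number of variates.
#' @param size trials per variate (scalar or vector).
#' @param mu mean success probability.
#' @param rho overdispersion in [0, 1).
#' @param seed integer seed; required.
#' @return integer vector of successes.
#' @export
rbetabinom <- function(n_draws, size, mu, rho, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)", call. = FALSE)
  size <- rep_len(size, n_draws)
  with_seed(seed, {
    p <- if (rho < 1e-10) rep(mu, n_draws) else
      rbeta(n_draws, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)
    rbinom(n_draws, size, p)
  })
}

#' Fit a global beta-binomial null model to pooled heterozygote counts
#'
#' Maximizes the summed beta-binomial log-likelihood of the pooled per-SNP
#' (k, n) pairs over mean `mu` in (0, 1) and overdispersion `rho` in
#' [0, 0.99], with method-of-moments initialization. One model is fit per
#' dataset. A fit pinned at a boundary (e.g. every SNP fully reference) is
#' flagged `degenerate`.
#'
#' @param pooled data.frame from [pool_het_counts()] with columns k, n.
#' @param min_snps minimum number of SNPs required (default 10).
#' @return object of class `BetaBinomialModel`: list with mu, rho, alpha,
#'   beta, loglik, n_snps, converged, degenerate.
#' @export
fit_beta_binomial <- function(pooled, min_snps = 10L) {
  pooled <- pooled[pooled$n >= 1, , drop = FALSE]
  if (nrow(pooled) < min_snps) {
    stop(sprintf("need at least %d SNPs with reads to fit (have %d)",
                 min_snps, nrow(pooled)), call. = FALSE)
  }
  k <- pooled$k
  n <- pooled$n

  # method-of-moments start: mu from the pooled fraction, rho from the
  # excess of the per-SNP fraction variance over binomial
  mu0 <- min(max(sum(k) / sum(n), 1e-3), 1 - 1e-3)
  f <- k / n
  nbar <- mean(n)
  v <- stats::var(f)
  rho0 <- if (is.na(v) || nbar <= 1) 0.01 else
    (v * nbar / (mu0 * (1 - mu0)) - 1) / (nbar - 1)
  rho0 <- min(max(rho0, 1e-4), 0.9)

  negll <- function(par) {
    mu <- plogis(par[1])
    rho <- plogis(par[2]) * 0.99
    -sum(dbetabinom(k, n, mu, rho, log = TRUE))
  }
  fit <- optim(c(qlogis(mu0), qlogis(rho0 / 0.99)), negll,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  mu <- plogis(fit$par[1])
  rho <- plogis(fit$par[2]) * 0.99

  # boundary refinement: if rho heads to the lower edge, compare against the
  # exact binomial fit
  ll_bin <- sum(dbinom(k, n, sum(k) / sum(n), log = TRUE))
  if (rho < 1e-4 || -fit$value < ll_bin) {
    if (ll_bin >= -fit$value) {
      mu <- sum(k) / sum(n)
      rho <- 0
      fit$value <- -ll_bin
    }
  }
  degenerate <- mu > 1 - 1e-6 || mu < 1e-6 || all(k == n) || all(k == 0)
  if (all(k == n)) mu <- 1 - 1e-6
  if (all(k == 0)) mu <- 1e-6

  model <- list(
    mu = mu, rho = rho,
    alpha = if (rho > 0) mu * (1 - rho) / rho else NA_real_,
    beta = if (rho > 0) (1 - mu) * (1 - rho) / rho else NA_real_,
    loglik = -fit$value,
    n_snps = nrow(pooled),
    converged = fit$convergence == 0L,
    degenerate = degenerate
  )
  class(model) <- "BetaBinomialModel"
  model
}

#' @export
print.BetaBinomialModel <- function(x, ...) {
  cat(sprintf(
    "BetaBinomialModel: mu = %.4f, rho = %.4f (n_snps = %d, loglik = %.1f)%s\n",
    x$mu, x$rho, x$n_snps, x$loglik,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Exact two-sided allelic-imbalance test under a beta-binomial null
#'
#' Minimum-likelihood two-sided exact p: the sum of `P(k' | n, mu, rho)`
#' over all outcomes `k'` no more probable than the observed `k` (with a
#' `1 + 1e-7` slack factor against floating-point ties). Always in (0, 1].
#'
#' @param k observed reference reads (vectorized).
#' @param n total reads.
#' @param model a `BetaBinomialModel` (or list with mu, rho).
#' @return two-sided p-value(s).
#' @export
test_allelic_imbalance <- function(k, n, model) {
  if (any(k > n)) stop("k cannot exceed n", call. = FALSE)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  mapply(function(ki, ni) {
    pmf <- dbetabinom(0:ni, ni, model$mu, model$rho)
    p_obs <- pmf[ki + 1L]
    min(sum(pmf[pmf <= p_obs * (1 + 1e-7)]), 1)
  }, k, n)
}

#' Test every pooled SNP of a dataset for allelic imbalance
#'
#' Fits the global beta-binomial null, tests each SNP, and reports the skew
#' direction (sign of `k/n - mu`).
#'
#' @param pooled data.frame from [pool_het_counts()].
#' @param model optional pre-fit `BetaBinomialModel`; fitted from `pooled`
#'   when NULL.
#' @return data.frame: snp, k, n, n_hets, ref_fraction, p, direction
#'   ("ref", "alt", or "none" at exact balance).
#' @export
test_dataset_imbalance <- function(pooled, model = NULL) {
  if (is.null(model)) model <- fit_beta_binomial(pooled)
  p <- test_allelic_imbalance(pooled$k, pooled$n, model)
  dir <- ifelse(pooled$k / pooled$n > model$mu, "ref",
                ifelse(pooled$k / pooled$n < model$mu, "alt", "none"))
  cbind(pooled, data.frame(p = p, direction = dir, stringsAsFactors = FALSE))
}

#' Cross-dataset concordant allelic-imbalance calls
#'
#' SNPs significant (p below `p_cut`) in at least `min_datasets` datasets
#' with the same skew direction; SNPs whose direction is tied (`"none"`) in
#' a significant dataset are excluded.
#'
#' @param results data.frame with snp, dataset, p, direction (e.g. stacked
#'   outputs of [test_dataset_imbalance()] with a dataset column).
#' @param p_cut per-dataset significance cutoff (default 0.05).
#' @param min_datasets minimum concordant significant datasets (default 2).
#' @return data.frame: snp, direction, n_significant, datasets.
#' @export
concordance <- function(results, p_cut = 0.05, min_datasets = 2L) {
  sig <- results[!is.na(results$p) & results$p < p_cut &
                   results$direction != "none", , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(snp = character(0), direction = character(0),
                      n_significant = integer(0), datasets = character(0)))
  }
  out <- do.call(rbind, lapply(split(sig, sig$snp), function(df) {
    if (length(unique(df$direction)) != 1L || nrow(df) < min_datasets) {
      return(NULL)
    }
    data.frame(snp = df$snp[1], direction = df$direction[1],
               n_significant = nrow(df),
               datasets = paste(sort(df$dataset), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(snp = character(0), direction = character(0),
                      n_significant = integer(0), datasets = character(0)))
  }
  rownames(out) <- NULL
  out[order(out$snp), , drop = FALSE]
}
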