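# Synthetic-data generators. These emulate, at toy scale, the statistical
# structure of the study inputs: LD-block haplotypes standing in for a
# reference panel, annotation-weighted polygenic z-scores, negative-binomial
# ATAC element counts with spiked condition effects, beta-binomial allelic
# read counts, and an element atlas with per-biosample activity Z-scores.
# Every generator is a pure function of its arguments including `seed`, and
# serializes its ground truth alongside the data.

#' Simulate a haplotype reference panel with block LD structure
#'
#' LD is produced by a founder-haplotype model: each LD block has a small set
#' of founder haplotypes; every sampled haplotype copies one founder and
#' flips each site independently at `mutation_rate`. This yields strong,
#' controllable within-block correlation and independence across blocks --
#' all the downstream math (r-squared, LD scores) needs. Monomorphic SNPs are
#' dropped and counted in `attr(panel, "n_monomorphic_dropped")`.
#'
#' Blocks are laid out on one synthetic chromosome, 100 bp between SNPs
#' within a block and a 1 Mb gap between blocks, so a sub-megabase LD window
#' never spans two blocks.
#'
#' @param n_individuals number of diploid individuals (>= 2); the panel has
#'   `2 * n_individuals` haplotypes.
#' @param n_blocks number of independent LD blocks.
#' @param snps_per_block SNPs simulated per block (before monomorphic drop).
#' @param n_founders_per_block founder haplotypes per block (>= 2); fewer
#'   founders means tighter LD.
#' @param mutation_rate per-site, per-haplotype flip probability.
#' @param seed integer seed; required.
#' @return An object of class `HaplotypePanel`: a list with `haplotypes`
#'   (binary matrix, haplotypes x SNPs, 0 = ref, 1 = alt) and `snp_meta`
#'   (data.frame with snp, chrom, pos, ref, alt, block).
#' @export
simulate_haplotype_panel <- function(n_individuals, n_blocks, snps_per_block,
                                     n_founders_per_block = 4L,
                                     mutation_rate = 0.01, seed) {
  n_individuals <- assert_count(n_individuals, "n_individuals", min = 2L)
  n_blocks <- assert_count(n_blocks, "n_blocks")
  snps_per_block <- assert_count(snps_per_block, "snps_per_block")
  n_founders_per_block <- assert_count(n_founders_per_block,
                                       "n_founders_per_block", min = 2L)
  mutation_rate <- assert_prob(mutation_rate, "mutation_rate")
  if (missing(seed)) stop("'seed' is required", call. = FALSE)

  n_hap <- 2L * n_individuals
  m <- n_blocks * snps_per_block
  with_seed(seed, {
    haps <- matrix(0L, nrow = n_hap, ncol = m)
    for (b in seq_len(n_blocks)) {
      cols <- (b - 1L) * snps_per_block + seq_len(snps_per_block)
      founders <- matrix(
        rbinom(n_founders_per_block * snps_per_block, 1L, 0.5),
        nrow = n_founders_per_block
      )
      pick <- sample.int(n_founders_per_block, n_hap, replace = TRUE)
      block <- founders[pick, , drop = FALSE]
      if (mutation_rate > 0) {
        flips <- matrix(rbinom(n_hap * snps_per_block, 1L, mutation_rate),
                        nrow = n_hap)
        block <- (block + flips) %% 2L
      }
      haps[, cols] <- block
    }
    pos <- as.integer(rep((seq_len(n_blocks) - 1L) * 1e6, each = snps_per_block) +
                        rep(seq_len(snps_per_block) * 100L, times = n_blocks))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

    freq <- colMeans(haps)
    keep <- freq > 0 & freq < 1
    panel <- list(
      haplotypes = haps[, keep, drop = FALSE],
      snp_meta = data.frame(
        snp = sprintf("snp%05d", which(keep)),
        chrom = "chrS",
        pos = pos[keep],
        ref = ref[keep],
        alt = unname(alt[keep]),
        block = rep(seq_len(n_blocks), each = snps_per_block)[keep],
        stringsAsFactors = FALSE
      )
    )
    colnames(panel$haplotypes) <- panel$snp_meta$snp
    attr(panel, "n_monomorphic_dropped") <- sum(!keep)
    class(panel) <- "HaplotypePanel"
    panel
  })
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf("HaplotypePanel: %d haplotypes x %d SNPs in %d block(s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              length(unique(x$snp_meta$block))))
  invisible(x)
}

#' Simulate GWAS summary statistics under an annotation-weighted model
#'
#' Generates z-scores directly from the LD-aware multivariate normal that
#' stratified LD-score regression assumes, rather than via individual-level
#' phenotypes: true per-SNP effects are drawn `beta_j ~ N(0, sum_C tau_C *
#' a_jC)` on the standardized-genotype scale, and per LD block
#' `z = sqrt(N) R beta + eps`, `eps ~ N(0, R)`, with `R` the block SNP
#' correlation matrix from the panel.
#'
#' @param panel a `HaplotypePanel`.
#' @param annotations binary SNP x annotation matrix (rows follow
#'   `panel$snp_meta`); defaults to a single all-SNPs annotation.
#' @param tau per-annotation per-SNP-heritability coefficients.
#' @param N GWAS sample size (N = 0 gives pure null z ~ N(0, R)).
#' @param seed integer seed; required.
#' @return list with `stats` (data.frame: snp, chrom, pos, ref, alt, z, chi2,
#'   beta_hat, se, p, n) and `truth` (list with true `beta`, `tau`,
#'   per-SNP variance).
#' @export
simulate_gwas_summary <- function(panel, annotations = NULL, tau, N, seed) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  m <- ncol(panel$haplotypes)
  if (is.null(annotations)) {
    annotations <- matrix(1, nrow = m, ncol = 1,
                          dimnames = list(NULL, "base"))
  }
  annotations <- as.matrix(annotations)
  if (nrow(annotations) != m) stop("annotation rows must match panel SNPs")
  if (length(tau) != ncol(annotations)) {
    stop("length(tau) must equal the number of annotation columns")
  }
  if (N < 0) stop("'N' must be non-negative")
  if (missing(seed)) stop("'seed' is required", call. = FALSE)

  sigma2 <- as.vector(annotations %*% tau)
  if (any(sigma2 < -1e-12)) {
    bad <- panel$snp_meta$snp[sigma2 < -1e-12]
    stop(sprintf("negative per-SNP variance for SNP(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  sigma2 <- pmax(sigma2, 0)

  with_seed(seed, {
    beta <- rnorm(m, 0, sqrt(sigma2))
    z <- numeric(m)
    for (b in unique(panel$snp_meta$block)) {
      idx <- which(panel$snp_meta$block == b)
      R <- cor(panel$haplotypes[, idx, drop = FALSE])
      ev <- eigen(R, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(idx))
      eps <- as.vector(L %*% rnorm(length(idx)))
      z[idx] <- sqrt(N) * as.vector(R %*% beta[idx]) + eps
    }
    se <- if (N > 0) 1 / sqrt(N) else NA_real_
    stats <- data.frame(
      snp = panel$snp_meta$snp,
      chrom = panel$snp_meta$chrom,
      pos = panel$snp_meta$pos,
      ref = panel$snp_meta$ref,
      alt = panel$snp_meta$alt,
      z = z,
      chi2 = z^2,
      beta_hat = if (N > 0) z / sqrt(N) else NA_real_,
      se = se,
      p = 2 * pnorm(-abs(z)),
      n = N,
      stringsAsFactors = FALSE
    )
    list(stats = stats,
         truth = list(beta = beta, tau = tau, sigma2 = sigma2))
  })
}

#' Simulate an ATAC-seq element count matrix with spiked condition effects
#'
#' Negative-binomial counts for a two-group design. Baseline log2 means are
#' uniform over `baseline_logmean_range`; per-sample library-size factors are
#' log-normal; a random `spike_fraction` of elements have their group-2 mean
#' shifted by `spike_log2fc`.
#'
#' @param n_elements number of elements.
#' @param group_sizes integer pair: samples in group 1 and group 2.
#' @param baseline_logmean_range interval of baseline log2 mean counts.
#' @param dispersion NB dispersion (1/size); variance = mu + dispersion*mu^2.
#' @param spike_fraction fraction of elements that are truly differential.
#' @param spike_log2fc log2 fold change applied to spiked elements in group 2.
#' @param seed integer seed; required.
#' @return list with `counts` (elements x samples integer matrix), `groups`
#'   (condition factor), `size_factors`, and `truth` (data.frame: element,
#'   spiked, log2fc).
#' @export
simulate_atac_counts <- function(n_elements, group_sizes = c(10L, 11L),
                                 baseline_logmean_range = c(4, 9),
                                 dispersion = 0.1, spike_fraction = 0.05,
                                 spike_log2fc = 2, seed) {
  n_elements <- assert_count(n_elements, "n_elements")
  if (length(group_sizes) != 2L || any(group_sizes < 1L)) {
    stop("'group_sizes' must be two counts >= 1", call. = FALSE)
  }
  if (dispersion <= 0) stop("'dispersion' must be > 0", call. = FALSE)
  spike_fraction <- assert_prob(spike_fraction, "spike_fraction")
  if (missing(seed)) stop("'seed' is required", call. = FALSE)

  n_s <- sum(group_sizes)
  groups <- factor(rep(c("g1", "g2"), times = group_sizes))
  with_seed(seed, {
    base_log2 <- runif(n_elements, baseline_logmean_range[1],
                       baseline_logmean_range[2])
    sf <- 2^rnorm(n_s, 0, 0.25)
    n_spiked <- round(spike_fraction * n_elements)
    spiked <- rep(FALSE, n_elements)
    if (n_spiked > 0) spiked[sample.int(n_elements, n_spiked)] <- TRUE
    log2fc <- ifelse(spiked, spike_log2fc, 0)

    mu <- outer(2^base_log2, sf)
    mu[, groups == "g2"] <- mu[, groups == "g2", drop = FALSE] *
      2^log2fc
    counts <- matrix(
      rnbinom(n_elements * n_s, mu = as.vector(mu), size = 1 / dispersion),
      nrow = n_elements
    )
    ids <- sprintf("el%05d", seq_len(n_elements))
    dimnames(counts) <- list(ids, sprintf("s%02d", seq_len(n_s)))
    list(
      counts = counts,
      groups = groups,
      size_factors = sf,
      truth = data.frame(element = ids, spiked = spiked, log2fc = log2fc,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate per-(SNP, individual) allelic read counts
#'
#' Each (SNP, individual) pair is heterozygous with probability `het_rate`,
#' else homozygous (ref or alt equally). Read depth is Poisson; for
#' heterozygotes the reference read count is beta-binomial with mean `theta`
#' and overdispersion `rho` (`rho = 0` degenerates to binomial); homozygote
#' reads all carry one allele.
#'
#' @param n_snps number of SNPs.
#' @param n_individuals number of individuals.
#' @param depth_mean mean Poisson read depth per (SNP, individual).
#' @param theta true reference-allele fraction in heterozygotes; scalar or
#'   per-SNP vector (spiked SNPs carry theta != 0.5).
#' @param rho beta-binomial overdispersion in [0, 1).
#' @param het_rate probability a (SNP, individual) pair is heterozygous.
#' @param seed integer seed; required.
#' @return list with `table` (data.frame: snp, individual, ref_reads,
#'   alt_reads) and `truth` (data.frame: snp, theta, rho).
#' @export
simulate_allele_counts <- function(n_snps, n_individuals, depth_mean = 20,
                                   theta = 0.5, rho = 0.05, het_rate = 0.4,
                                   seed) {
  n_snps <- assert_count(n_snps, "n_snps")
  n_individuals <- assert_count(n_individuals, "n_individuals")
  if (any(theta <= 0) || any(theta >= 1)) {
    stop("'theta' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)", call. = FALSE)
  het_rate <- assert_prob(het_rate, "het_rate")
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  theta <- rep_len(theta, n_snps)

  with_seed(seed, {
    n_cell <- n_snps * n_individuals
    snp <- rep(sprintf("snp%05d", seq_len(n_snps)), each = n_individuals)
    theta_cell <- rep(theta, each = n_individuals)
    indiv <- rep(sprintf("ind%03d", seq_len(n_individuals)), times = n_snps)
    is_het <- runif(n_cell) < het_rate
    depth <- rpois(n_cell, depth_mean)

    ref <- integer(n_cell)
    het_i <- which(is_het & depth > 0)
    if (rho > 0) {
      a <- theta_cell[het_i] * (1 - rho) / rho
      b <- (1 - theta_cell[het_i]) * (1 - rho) / rho
      p <- rbeta(length(het_i), a, b)
    } else {
      p <- theta_cell[het_i]
    }
    ref[het_i] <- rbinom(length(het_i), depth[het_i], p)
    hom_i <- which(!is_het & depth > 0)
    hom_ref <- runif(length(hom_i)) < 0.5
    ref[hom_i] <- ifelse(hom_ref, depth[hom_i], 0L)

    list(
      table = data.frame(
        snp = snp, individual = indiv,
        ref_reads = ref, alt_reads = depth - ref,
        stringsAsFactors = FALSE
      ),
      truth = data.frame(
        snp = sprintf("snp%05d", seq_len(n_snps)),
        theta = theta, rho = rho, stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate a regulatory-element atlas with per-biosample activity Z-scores
#'
#' Non-overlapping, sorted 200-bp intervals on a synthetic chromosome. Each
#' (element, biosample) cell is active with probability `active_fraction`;
#' active cells draw Z above the 1.64 activity threshold (1.64 + Exp(1)),
#' inactive cells draw standard normal truncated below 1.64, so the expected
#' fraction of cells exceeding 1.64 equals `active_fraction` exactly.
#'
#' @param n_elements number of elements.
#' @param biosamples character vector of biosample names.
#' @param active_fraction target fraction of (element, biosample) cells
#'   exceeding Z = 1.64; in (0, 1].
#' @param seed integer seed; required.
#' @return An `ElementAtlas`: list with `elements` (data.frame: id, chrom,
#'   start, end; 0-based half-open) and `zscores` (element x biosample
#'   matrix).
#' @export
simulate_element_atlas <- function(n_elements, biosamples = c("b1", "b2", "b3", "b4"),
                                   active_fraction = 0.3, seed) {
  n_elements <- assert_count(n_elements, "n_elements")
  active_fraction <- assert_prob(active_fraction, "active_fraction")
  if (active_fraction == 0) stop("'active_fraction' must be > 0", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)

  with_seed(seed, {
    ids <- sprintf("el%05d", seq_len(n_elements))
    start <- (seq_len(n_elements) - 1L) * 500L
    elements <- data.frame(
      id = ids, chrom = "chrS", start = start, end = start + 200L,
      stringsAsFactors = FALSE
    )
    n_cell <- n_elements * length(biosamples)
    active <- runif(n_cell) < active_fraction
    z <- numeric(n_cell)
    z[active] <- 1.64 + rexp(sum(active)) + 1e-9
    # inactive cells: N(0,1) truncated below the threshold
    z[!active] <- stats::qnorm(runif(sum(!active)) * pnorm(1.64))
    zscores <- matrix(z, nrow = n_elements,
                      dimnames = list(ids, biosamples))
    atlas <- list(elements = elements, zscores = zscores)
    class(atlas) <- "ElementAtlas"
    atlas
  })
}

#' @export
print.ElementAtlas <- function(x, ...) {
  cat(sprintf("ElementAtlas: %d elements x %d biosample(s)\n",
              nrow(x$elements), ncol(x$zscores)))
  invisible(x)
}
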