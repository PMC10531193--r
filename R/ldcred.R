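# Credible-set construction: LD expansion around lead variants, exact
# single-causal Bayesian fine-mapping via approximate Bayes factors, and
# coding/noncoding locus classification against exon annotations.

#' Haplotype-based r-squared between two SNPs
#'
#' `r2 = D^2 / (pA (1 - pA) pB (1 - pB))` with `D = pAB - pA pB` computed
#' from phased haplotype frequencies; identical to the squared Pearson
#' correlation of the two haplotype indicator vectors.
#'
#' @param panel a `HaplotypePanel`.
#' @param snp_i,snp_j SNP ids (or column indices) in the panel.
#' @return r-squared in [0, 1].
#' @export
compute_r2 <- function(panel, snp_i, snp_j) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  hi <- panel$haplotypes[, snp_i]
  hj <- panel$haplotypes[, snp_j]
  r2_from_haplotypes(hi, hj)
}

r2_from_haplotypes <- function(hi, hj) {
  pA <- mean(hi)
  pB <- mean(hj)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("r2 is undefined for a monomorphic SNP", call. = FALSE)
  }
  D <- mean(hi * hj) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Expand a lead variant into its LD set
#'
#' Returns all panel SNPs within `locus_window` bp of the lead whose
#' r-squared with the lead strictly exceeds `threshold`, plus the lead
#' itself, sorted by position. The inequality is strict: a partner at
#' exactly the threshold is excluded.
#'
#' @param lead lead variant id (must be in the panel).
#' @param panel a `HaplotypePanel`.
#' @param locus_window half-width of the locus in bp (default 500 kb).
#' @param threshold r-squared cutoff (default 0.7, strict `>`).
#' @return data.frame with snp, chrom, pos, r2, sorted by position.
#' @export
ld_expand <- function(lead, panel, locus_window = 5e5, threshold = 0.7) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  meta <- panel$snp_meta
  li <- match(lead, meta$snp)
  if (is.na(li)) stop(sprintf("lead variant '%s' not found in panel", lead),
                      call. = FALSE)
  in_window <- meta$chrom == meta$chrom[li] &
    abs(meta$pos - meta$pos[li]) <= locus_window
  idx <- which(in_window)
  r2 <- vapply(idx, function(j) {
    if (j == li) return(1)
    tryCatch(compute_r2(panel, li, j), error = function(e) NA_real_)
  }, numeric(1))
  keep <- idx == li | (!is.na(r2) & r2 > threshold)
  out <- data.frame(
    snp = meta$snp[idx][keep],
    chrom = meta$chrom[idx][keep],
    pos = meta$pos[idx][keep],
    r2 = r2[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$pos), , drop = FALSE]
}

#' Wakefield approximate Bayes factor for a single association
#'
#' `ABF = sqrt(se^2 / (se^2 + W)) * exp(z^2 W / (2 (se^2 + W)))` with
#' `z = beta / se`; the Bayes factor for association against the null under
#' a `N(0, W)` effect prior. Computed in log space.
#'
#' @param beta effect estimate.
#' @param se standard error (> 0).
#' @param W prior effect variance (> 0); default 0.04 (prior SD 0.2 on the
#'   log-odds scale), the standard single-causal prior.
#' @return the ABF (positive).
#' @export
wakefield_abf <- function(beta, se, W = 0.04) {
  exp(wakefield_log_abf(beta, se, W))
}

wakefield_log_abf <- function(beta, se, W = 0.04) {
  if (any(se <= 0)) stop("'se' must be > 0", call. = FALSE)
  if (any(W <= 0)) stop("'W' must be > 0", call. = FALSE)
  z <- beta / se
  0.5 * log(se^2 / (se^2 + W)) + z^2 * W / (2 * (se^2 + W))
}

#' Exact single-causal posterior probabilities for one locus
#'
#' Under the assumption of exactly one causal SNP per locus with a flat
#' prior over SNPs, the posterior probability of SNP j being causal is its
#' ABF normalized over the locus: `PP_j = ABF_j / sum_k ABF_k`. Normalized
#' in log space for stability.
#'
#' @param stats data.frame with columns `beta_hat` (or `beta`) and `se`;
#'   one row per locus SNP.
#' @param W prior effect variance.
#' @return numeric vector of posterior probabilities summing to 1.
#' @export
single_causal_posteriors <- function(stats, W = 0.04) {
  if (NROW(stats) == 0L) stop("empty locus: no SNPs to fine-map", call. = FALSE)
  beta <- stats$beta_hat %||% stats$beta
  labf <- wakefield_log_abf(beta, stats$se, W)
  labf <- labf - max(labf)
  pp <- exp(labf) / sum(exp(labf))
  names(pp) <- stats$snp
  pp
}

#' Build a credible set from posterior probabilities
#'
#' Sorts PPs descending (ties broken by ascending position), takes the
#' smallest prefix whose cumulative PP reaches `coverage`, then drops
#' members with individual PP at or below `min_pp` (the ">1% posterior"
#' retention rule).
#'
#' @param pps named numeric vector of posterior probabilities (must sum to 1
#'   within 1e-6).
#' @param pos optional positions for deterministic tie-breaking.
#' @param coverage cumulative posterior mass to capture (default 0.95).
#' @param min_pp retain only members with PP strictly above this (default
#'   0.01).
#' @return data.frame with snp, pp, cum_pp for the retained members.
#' @export
build_credible_set <- function(pps, pos = NULL, coverage = 0.95, min_pp = 0.01) {
  if (abs(sum(pps) - 1) > 1e-6) {
    stop("posterior probabilities must sum to 1 (within 1e-6)", call. = FALSE)
  }
  if (is.null(pos)) pos <- seq_along(pps)
  ord <- order(-pps, pos)
  pp_sorted <- pps[ord]
  cum <- cumsum(pp_sorted)
  n_take <- which(cum >= coverage - 1e-12)[1]
  if (is.na(n_take)) n_take <- length(pps)
  take <- seq_len(n_take)
  keep <- pp_sorted[take] > min_pp
  data.frame(
    snp = names(pp_sorted)[take][keep] %||% as.character(ord[take][keep]),
    pp = unname(pp_sorted[take][keep]),
    cum_pp = unname(cum[take][keep]),
    stringsAsFactors = FALSE
  )
}

#' Fine-map one locus and tag members against the LD set
#'
#' Convenience wrapper: computes single-causal posteriors, builds the
#' credible set, and tags each retained variant by provenance -- `LD` (LD
#' set only), `FINEMAP` (credible set only), or `both`.
#'
#' @param stats per-locus summary statistics (snp, chrom, pos, beta_hat, se).
#' @param ld_set optional data.frame from [ld_expand()] (columns snp, r2).
#' @param W prior effect variance.
#' @param coverage,min_pp credible-set parameters; see
#'   [build_credible_set()].
#' @return data.frame with snp, pos, pp, r2, source.
#' @export
finemap_locus <- function(stats, ld_set = NULL, W = 0.04,
                          coverage = 0.95, min_pp = 0.01) {
  pp <- single_causal_posteriors(stats, W)
  cs <- build_credible_set(pp, pos = stats$pos, coverage = coverage,
                           min_pp = min_pp)
  ld_snps <- if (is.null(ld_set)) character(0) else ld_set$snp
  all_snps <- union(cs$snp, ld_snps)
  out <- data.frame(snp = all_snps, stringsAsFactors = FALSE)
  out$pos <- stats$pos[match(out$snp, stats$snp)]
  out$pp <- cs$pp[match(out$snp, cs$snp)]
  out$r2 <- if (is.null(ld_set)) NA_real_ else
    ld_set$r2[match(out$snp, ld_set$snp)]
  out$source <- ifelse(out$snp %in% cs$snp & out$snp %in% ld_snps, "both",
                       ifelse(out$snp %in% cs$snp, "FINEMAP", "LD"))
  out[order(out$pos), , drop = FALSE]
}

#' Classify a locus as coding or noncoding
#'
#' A locus is coding iff at least one credible-set member's (1-based)
#' position falls inside a (0-based half-open) coding exon: position `p`
#' intersects exon `[s, e)` iff `s <= p - 1 < e`.
#'
#' @param members data.frame of credible-set members with chrom and pos
#'   (1-based).
#' @param exons data.frame of exon intervals with chrom, start, end (0-based
#'   half-open).
#' @return list with `class` ("coding" or "noncoding") and `coding_variants`
#'   (character vector of member snp ids inside exons).
#' @export
classify_locus_coding <- function(members, exons) {
  if (NROW(exons) == 0L || NROW(members) == 0L) {
    return(list(class = "noncoding", coding_variants = character(0)))
  }
  hits <- intersect_variants_elements(
    data.frame(snp = members$snp, chrom = members$chrom, pos = members$pos,
               stringsAsFactors = FALSE),
    data.frame(id = exons$id %||% sprintf("exon%d", seq_len(nrow(exons))),
               chrom = exons$chrom, start = exons$start, end = exons$end,
               stringsAsFactors = FALSE)
  )
  coding <- members$snp[lengths(hits) > 0]
  list(
    class = if (length(coding) > 0) "coding" else "noncoding",
    coding_variants = coding
  )
}
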