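# Desk-scale stratified LD-score regression: annotation-specific LD scores
# from the haplotype panel, weighted chi-squared regression for
# per-annotation heritability coefficients with block-jackknife standard
# errors, and enrichment estimates with conditional tests.

#' Annotation-stratified LD scores
#'
#' For SNP j and annotation C, `l(j, C)` is the sum over SNPs k within
#' `window_bp` of j (same chromosome, self included) of
#' `a_kC * r2_adj(j, k)`, where `r2_adj = r2 - (1 - r2)/(n_hap - 2)` when
#' `adjust_bias` (the standard finite-sample correction; the self term stays
#' exactly 1) and raw r-squared otherwise.
#'
#' @param panel a `HaplotypePanel`.
#' @param annotations binary SNP x annotation matrix (rows follow
#'   `panel$snp_meta`).
#' @param window_bp LD window half-width in bp (default 1e5).
#' @param adjust_bias apply the finite-sample r-squared correction?
#' @return object of class `LDScoreTable`: list with `ldscores` (SNP x
#'   annotation matrix), `M` (total SNPs), `M_annot` (per-annotation SNP
#'   counts), and `snp_meta`.
#' @export
compute_ld_scores <- function(panel, annotations, window_bp = 1e5,
                              adjust_bias = TRUE) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  annotations <- as.matrix(annotations)
  m <- ncol(panel$haplotypes)
  if (nrow(annotations) != m) stop("annotation rows must match panel SNPs")
  n_hap <- nrow(panel$haplotypes)
  if (adjust_bias && n_hap <= 2) {
    stop("bias adjustment requires more than 2 haplotypes", call. = FALSE)
  }
  X <- scale(panel$haplotypes)
  pos <- panel$snp_meta$pos
  chrom <- panel$snp_meta$chrom
  L <- matrix(0, m, ncol(annotations),
              dimnames = list(panel$snp_meta$snp, colnames(annotations)))
  for (j in seq_len(m)) {
    nb <- which(chrom == chrom[j] & abs(pos - pos[j]) <= window_bp)
    r <- crossprod(X[, nb, drop = FALSE], X[, j]) / (n_hap - 1)
    r2 <- pmin(as.vector(r)^2, 1)
    if (adjust_bias) r2 <- r2 - (1 - r2) / (n_hap - 2)
    L[j, ] <- colSums(annotations[nb, , drop = FALSE] * r2)
  }
  out <- list(
    ldscores = L,
    M = m,
    M_annot = colSums(annotations),
    annotations = annotations,
    snp_meta = panel$snp_meta
  )
  class(out) <- "LDScoreTable"
  out
}

#' Stratified LD-score regression of chi-squared statistics
#'
#' Weighted least squares of per-SNP GWAS chi-squared on `N * l(j, C)`
#' across annotations with a free intercept. Weights are
#' `1 / (2 (N l_total,j hbar2 / M + 1)^2)` -- the inverse of the approximate
#' chi-squared variance -- iterated once from an initial unweighted fit
#' (`hbar2` is the total-heritability estimate `sum_C tau_C M_C` of the
#' previous pass, clamped to [0, 1]). Standard errors come from a
#' delete-one-block jackknife over `n_blocks` contiguous SNP blocks.
#'
#' @param chi2 per-SNP chi-squared statistics, SNPs ordered by position.
#' @param ldscores an `LDScoreTable`.
#' @param N GWAS sample size.
#' @param n_blocks number of jackknife blocks (default 20 at desk scale).
#' @return list with `tau` (per-annotation coefficients), `intercept`,
#'   `se`, `intercept_se`, `jackknife` (leave-one-block-out coefficient
#'   matrix), `vcov`, `weights`, `h2_total`.
#' @export
regress_partitioned <- function(chi2, ldscores, N, n_blocks = 20L) {
  stopifnot(inherits(ldscores, "LDScoreTable"))
  n_blocks <- assert_count(n_blocks, "n_blocks", min = 2L)
  L <- ldscores$ldscores
  m <- nrow(L)
  if (length(chi2) != m) stop("chi2 length must match LD-score rows")
  X <- cbind(intercept = 1, N * L)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("singular design: collinear annotation(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }

  fit_wls <- function(w, rows = seq_len(m)) {
    Xw <- X[rows, , drop = FALSE] * sqrt(w[rows])
    yw <- chi2[rows] * sqrt(w[rows])
    qr.coef(qr(Xw), yw)
  }

  # pass 1: unweighted; pass 2: variance-based weights from pass-1 h2
  co0 <- fit_wls(rep(1, m))
  h2_0 <- min(max(sum(co0[-1] * ldscores$M_annot), 0), 1)
  l_total <- rowSums(L)
  w <- 1 / (2 * (N * l_total * h2_0 / ldscores$M + 1)^2)
  co <- fit_wls(w)

  blocks <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  jk <- t(vapply(seq_len(n_blocks), function(b) {
    fit_wls(w, rows = which(blocks != b))
  }, numeric(ncol(X))))
  jk_mean <- colMeans(jk)
  vcov <- (n_blocks - 1) / n_blocks *
    crossprod(sweep(jk, 2, jk_mean))
  se <- sqrt(diag(vcov))

  tau <- co[-1]
  names(tau) <- colnames(L)
  list(
    tau = tau,
    intercept = unname(co[1]),
    se = se[-1],
    intercept_se = unname(se[1]),
    jackknife = jk[, -1, drop = FALSE],
    jackknife_intercept = jk[, 1],
    vcov = vcov,
    weights = w,
    h2_total = sum(tau * ldscores$M_annot),
    n_blocks = n_blocks
  )
}

#' Heritability enrichment per annotation
#'
#' Per-SNP heritability is `h2_j = sum_C tau_C a_jC`; the enrichment of
#' annotation C is its heritability share over its SNP share,
#' `(h2_C / h2_total) / (M_C / M)`. Standard errors are propagated through
#' the block jackknife (the enrichment is recomputed from each
#' leave-one-block-out coefficient vector), and the conditional p-value is
#' the two-sided normal tail of `tau_C / SE(tau_C)`. The all-SNPs
#' annotation has enrichment 1 by construction; when every tau is zero the
#' enrichment is undefined (0/0) and flagged.
#'
#' @param fit output of [regress_partitioned()].
#' @param ldscores the `LDScoreTable` used in the fit.
#' @return data.frame of class `EnrichmentResult`: annotation, tau, tau_se,
#'   M_annot, prop_snps, prop_h2, enrichment, enrichment_se, conditional_z,
#'   conditional_p, defined.
#' @export
enrichment_estimates <- function(fit, ldscores) {
  A <- ldscores$annotations
  M <- ldscores$M
  M_C <- ldscores$M_annot
  enr_from_tau <- function(tau) {
    h2_snp <- as.vector(A %*% tau)
    h2_tot <- sum(h2_snp)
    h2_C <- as.vector(crossprod(A, h2_snp))
    if (abs(h2_tot) < 1e-300) return(rep(NA_real_, ncol(A)))
    (h2_C / h2_tot) / (M_C / M)
  }
  enr <- enr_from_tau(fit$tau)
  jk_enr <- t(apply(fit$jackknife, 1, enr_from_tau))
  if (ncol(A) == 1L) jk_enr <- matrix(jk_enr, ncol = 1L)
  enr_se <- vapply(seq_len(ncol(A)), function(c_) {
    v <- jk_enr[, c_]
    if (any(is.na(v))) return(NA_real_)
    sqrt((fit$n_blocks - 1) / fit$n_blocks * sum((v - mean(v))^2))
  }, numeric(1))

  z <- fit$tau / fit$se
  skipped <- M_C == 0
  if (any(skipped)) {
    warning(sprintf("annotation(s) with no SNPs skipped: %s",
                    paste(colnames(A)[skipped], collapse = ", ")))
  }
  out <- data.frame(
    annotation = colnames(A) %||% sprintf("annot%d", seq_len(ncol(A))),
    tau = unname(fit$tau),
    tau_se = unname(fit$se),
    M_annot = unname(M_C),
    prop_snps = unname(M_C / M),
    prop_h2 = unname(enr * M_C / M),
    enrichment = unname(enr),
    enrichment_se = unname(enr_se),
    conditional_z = unname(z),
    conditional_p = unname(2 * pnorm(-abs(z))),
    defined = !is.na(enr) & !skipped,
    stringsAsFactors = FALSE
  )
  out[skipped, c("enrichment", "enrichment_se")] <- NA_real_
  class(out) <- c("EnrichmentResult", class(out))
  out
}
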