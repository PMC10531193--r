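# Motif ref-vs-alt delta scoring, eQTL-based gene-support classification,
# and end-to-end pipeline orchestration.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Accepts per-position base counts or probabilities (4 x L, rows A/C/G/T),
#' adds a pseudocount, and renormalizes each column to sum to 1 so every
#' probability is strictly positive.
#'
#' @param id motif id.
#' @param mat 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param bg background base frequencies (default uniform).
#' @param pseudocount added to each probability before renormalization
#'   (default 0.001).
#' @return object of class `PWM`: list with id, prob (4 x L), bg, length.
#' @export
pwm <- function(id, mat, bg = rep(0.25, 4), pseudocount = 0.001) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM matrix must have 4 rows (A, C, G, T)")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  prob <- sweep(mat, 2, colSums(mat), "/")
  prob <- prob + pseudocount
  prob <- sweep(prob, 2, colSums(prob), "/")
  rownames(prob) <- BASES
  out <- list(id = id, prob = prob, bg = setNames(bg, BASES),
              length = ncol(prob))
  class(out) <- "PWM"
  out
}

#' Read motifs from a JASPAR-style tabular file
#'
#' Minimal JASPAR format: a `>id` header line followed by four lines
#' `A [ n n ... ]` etc.
#'
#' @param path motif file.
#' @param ... passed to [pwm()].
#' @return named list of `PWM` objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  motifs <- lapply(starts, function(s) {
    id <- sub("^>\\s*", "", lines[s])
    id <- strsplit(id, "\\s+")[[1]][1]
    rows <- lapply(lines[(s + 1):(s + 4)], function(r) {
      body <- sub("^\\s*[ACGTacgt]", "", r)
      as.numeric(regmatches(body, gregexpr("[0-9.eE+-]+", body))[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop(sprintf("motif '%s': unequal row lengths", id), call. = FALSE)
    }
    pwm(id, do.call(rbind, rows), ...)
  })
  setNames(motifs, vapply(motifs, `[[`, character(1), "id"))
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

#' Log2-odds PWM score of a sequence
#'
#' `sum_i log2(P_i(seq_i) / bg(seq_i))` over the motif columns. With
#' `both_strands = TRUE` the reverse complement is scored too and the
#' maximum returned.
#'
#' @param seq base string whose length equals the motif length.
#' @param pwm_obj a `PWM`.
#' @param both_strands score both orientations and take the max?
#' @return log2-odds score.
#' @export
pwm_score <- function(seq, pwm_obj, both_strands = FALSE) {
  stopifnot(inherits(pwm_obj, "PWM"))
  bases <- strsplit(toupper(seq), "")[[1]]
  if (length(bases) != pwm_obj$length) {
    stop(sprintf("sequence length %d != motif length %d",
                 length(bases), pwm_obj$length), call. = FALSE)
  }
  if (!all(bases %in% BASES)) {
    stop("ambiguous or invalid base in sequence", call. = FALSE)
  }
  idx <- cbind(match(bases, BASES), seq_along(bases))
  fwd <- sum(log2(pwm_obj$prob[idx] / pwm_obj$bg[bases]))
  if (!both_strands) return(fwd)
  max(fwd, pwm_score(revcomp(toupper(seq)), pwm_obj, both_strands = FALSE))
}

#' Allelic delta in PWM score
#'
#' With the motif alignment held fixed, rescoring the window after the
#' allele substitution reduces to the single-column log ratio
#' `delta = log2(P_offset(alt) / P_offset(ref))`. A negative delta predicts
#' decreased factor binding for the alternative allele.
#'
#' @param ref_window reference base string of motif length.
#' @param alt_allele alternative base at `offset`.
#' @param offset 1-based position of the variant within the window.
#' @param pwm_obj a `PWM`.
#' @return list with `delta`, `score_ref`, `score_alt`, and `prediction`
#'   ("decreased", "increased", or "neutral").
#' @export
pwm_delta_score <- function(ref_window, alt_allele, offset, pwm_obj) {
  stopifnot(inherits(pwm_obj, "PWM"))
  bases <- strsplit(toupper(ref_window), "")[[1]]
  if (offset < 1 || offset > length(bases)) {
    stop("'offset' must lie within the window", call. = FALSE)
  }
  alt_allele <- toupper(alt_allele)
  if (bases[offset] == alt_allele) {
    stop("alt allele equals the reference base at the offset", call. = FALSE)
  }
  score_ref <- pwm_score(ref_window, pwm_obj)
  alt_bases <- bases
  alt_bases[offset] <- alt_allele
  score_alt <- pwm_score(paste(alt_bases, collapse = ""), pwm_obj)
  delta <- score_alt - score_ref
  list(
    delta = delta, score_ref = score_ref, score_alt = score_alt,
    prediction = if (delta < 0) "decreased" else if (delta > 0) "increased"
      else "neutral"
  )
}

#' Classify genes by differential expression, GWAS, and ATAC support
#'
#' A gene has GWAS support iff one of its eQTL SNPs is a risk SNP (GWAS p
#' below `gwas_p_cut`), and ATAC support iff one of its eQTL SNPs falls
#' inside a differential regulatory element (element p below
#' `element_p_cut`). The differential tier comes from the expression FDR
#' (`fdr10` below the first tier, `fdr20` below the second, else `none`),
#' and the candidate flag marks non-differential genes carrying both
#' supports -- regulatory candidates missed by expression alone.
#'
#' @param diff_genes data.frame: gene, log2fc, q.
#' @param eqtls data.frame: gene, snp, chrom, pos (1-based), p.
#' @param gwas data.frame: snp, p.
#' @param diff_elements data.frame: id, chrom, start, end (0-based
#'   half-open), p.
#' @param fdr_tiers two FDR cutpoints (default 0.10, 0.20).
#' @param gwas_p_cut GWAS significance for an eQTL SNP (default 1e-6).
#' @param element_p_cut differential-element significance (default 0.01).
#' @return data.frame: gene, tier, gwas_support, atac_support, candidate,
#'   category.
#' @export
classify_gene_support <- function(diff_genes, eqtls, gwas, diff_elements,
                                  fdr_tiers = c(0.10, 0.20),
                                  gwas_p_cut = 1e-6, element_p_cut = 0.01) {
  sig_elements <- diff_elements[!is.na(diff_elements$p) &
                                  diff_elements$p < element_p_cut, ,
                                drop = FALSE]
  eqtl_in_sig <- if (nrow(eqtls) > 0 && nrow(sig_elements) > 0) {
    hits <- intersect_variants_elements(
      data.frame(snp = eqtls$snp, chrom = eqtls$chrom, pos = eqtls$pos,
                 stringsAsFactors = FALSE),
      sig_elements
    )
    lengths(hits) > 0
  } else rep(FALSE, nrow(eqtls))
  gwas_p <- setNames(gwas$p, gwas$snp)
  eqtl_gwas <- !is.na(gwas_p[eqtls$snp]) & gwas_p[eqtls$snp] < gwas_p_cut

  out <- do.call(rbind, lapply(seq_len(nrow(diff_genes)), function(i) {
    g <- diff_genes$gene[i]
    rows <- which(eqtls$gene == g)
    gwas_support <- any(eqtl_gwas[rows])
    atac_support <- any(eqtl_in_sig[rows])
    q <- diff_genes$q[i]
    tier <- if (!is.na(q) && q < fdr_tiers[1]) "fdr10"
      else if (!is.na(q) && q < fdr_tiers[2]) "fdr20" else "none"
    data.frame(
      gene = g, tier = tier,
      gwas_support = gwas_support, atac_support = atac_support,
      candidate = tier == "none" && gwas_support && atac_support,
      category = paste(c(if (tier != "none") "differential",
                         if (gwas_support) "gwas",
                         if (atac_support) "atac"), collapse = "+"),
      stringsAsFactors = FALSE
    )
  }))
  out$category[out$category == ""] <- "none"
  out
}

#' Default demo pipeline configuration
#'
#' All stages enabled on synthetic inputs at desk scale; every stage seed is
#' derived from the single top-level seed.
#'
#' @param seed integer master seed.
#' @param out_dir output directory (default tempdir subdirectory).
#' @return config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, out_dir = file.path(tempdir(), "regelex_demo")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(credible = TRUE, atlas = TRUE, diff = TRUE,
                  allelic = TRUE, ldsc = TRUE, permtest = TRUE),
    panel = list(n_individuals = 100L, n_blocks = 20L, snps_per_block = 25L,
                 n_founders_per_block = 4L, mutation_rate = 0.02),
    gwas = list(N = 10000L, tau_base = 2e-5, tau_annot = 2e-4,
                annot_fraction = 0.1),
    atac = list(n_elements = 500L, group_sizes = c(10L, 11L),
                dispersion = 0.1, spike_fraction = 0.05, spike_log2fc = 2),
    allelic = list(n_snps = 200L, n_individuals = 20L, depth_mean = 20,
                   rho = 0.05, het_rate = 0.4),
    atlas = list(n_elements = 500L,
                 biosamples = c("tcell1", "tcell2", "tcell3", "tcell4"),
                 active_fraction = 0.3),
    finemap = list(W = 0.04, coverage = 0.95, min_pp = 0.01, r2 = 0.7),
    permtest = list(n_perm = 2000L)
  )
}

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("seed", "out_dir", "stages")
  missing_f <- setdiff(required, names(config))
  if (length(missing_f) > 0) {
    stop(sprintf("config is missing required field(s): %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(config$seed)) stop("config$seed must be numeric",
                                     call. = FALSE)
  config
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes simulate -> credible sets -> atlas activity -> differential
#' accessibility -> allelic imbalance -> stratified LD-score regression ->
#' permutation enrichment, gated by `config$stages`, writing per-stage TSV
#' outputs plus a machine-readable JSON summary (with all seeds and
#' parameters) under `config$out_dir`. Reruns with the same config are
#' identical.
#'
#' @param config a config list from [demo_config()] (or a YAML file path
#'   with the same structure).
#' @return (invisibly) list with `summary` (also written as JSON) and the
#'   per-stage result objects.
#' @export
run_pipeline <- function(config = demo_config()) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  summary <- list(seed = seed, parameters = config[setdiff(names(config),
                                                           c("out_dir"))])
  results <- list()

  # --- simulate shared inputs -------------------------------------------
  pp <- config$panel
  panel <- simulate_haplotype_panel(
    pp$n_individuals, pp$n_blocks, pp$snps_per_block,
    pp$n_founders_per_block, pp$mutation_rate, seed = seed + 1L
  )
  m <- ncol(panel$haplotypes)
  gw <- config$gwas
  annot <- with_seed(seed + 2L, {
    a <- matrix(0, m, 2, dimnames = list(NULL, c("base", "focal")))
    a[, 1] <- 1
    a[sample.int(m, round(gw$annot_fraction * m)), 2] <- 1
    a
  })
  gwas <- simulate_gwas_summary(panel, annot,
                                tau = c(gw$tau_base, gw$tau_annot),
                                N = gw$N, seed = seed + 3L)
  results$panel <- panel
  results$gwas <- gwas

  # --- credible sets -----------------------------------------------------
  if (isTRUE(config$stages$credible)) {
    fm <- config$finemap
    lead <- gwas$stats$snp[which.max(gwas$stats$chi2)]
    lead_block <- panel$snp_meta$block[match(lead, panel$snp_meta$snp)]
    locus <- gwas$stats[panel$snp_meta$block == lead_block, , drop = FALSE]
    ld_set <- ld_expand(lead, panel, threshold = fm$r2)
    cs <- finemap_locus(locus, ld_set, W = fm$W, coverage = fm$coverage,
                        min_pp = fm$min_pp)
    write_tsv_table(cs, file.path(config$out_dir, "credible_set.tsv"))
    results$credible <- cs
    summary$credible <- list(lead = lead, n_members = nrow(cs),
                             n_finemap = sum(cs$source != "LD"),
                             n_ld = sum(cs$source != "FINEMAP"))
  }

  # --- atlas -------------------------------------------------------------
  if (isTRUE(config$stages$atlas)) {
    at <- config$atlas
    atlas <- simulate_element_atlas(at$n_elements, at$biosamples,
                                    at$active_fraction, seed = seed + 4L)
    active <- threshold_active_elements(atlas$zscores)
    write_atlas(atlas, file.path(config$out_dir, "atlas"))
    results$atlas <- atlas
    results$active_elements <- active
    summary$atlas <- list(n_elements = at$n_elements,
                          n_active = length(active))
  }

  # --- differential accessibility ---------------------------------------
  if (isTRUE(config$stages$diff)) {
    ac <- config$atac
    sim <- simulate_atac_counts(ac$n_elements, ac$group_sizes,
                                dispersion = ac$dispersion,
                                spike_fraction = ac$spike_fraction,
                                spike_log2fc = ac$spike_log2fc,
                                seed = seed + 5L)
    offs <- loess_normalize(sim$counts)
    diff <- test_differential(sim$counts, offs, sim$groups)
    write_tsv_table(diff, file.path(config$out_dir, "differential.tsv"))
    results$diff <- diff
    results$diff_truth <- sim$truth
    summary$diff <- list(
      n_tested = sum(diff$tested),
      n_q05 = sum(diff$q < 0.05, na.rm = TRUE),
      n_true_spiked = sum(sim$truth$spiked)
    )
  }

  # --- allelic imbalance -------------------------------------------------
  if (isTRUE(config$stages$allelic)) {
    al <- config$allelic
    spiked <- with_seed(seed + 6L,
                        sample.int(al$n_snps, round(0.05 * al$n_snps)))
    theta <- rep(0.5, al$n_snps)
    theta[spiked] <- 0.6
    sim <- simulate_allele_counts(al$n_snps, al$n_individuals,
                                  al$depth_mean, theta = theta, rho = al$rho,
                                  het_rate = al$het_rate, seed = seed + 7L)
    pooled <- pool_het_counts(sim$table)
    model <- fit_beta_binomial(pooled)
    tested <- test_dataset_imbalance(pooled, model)
    write_tsv_table(tested, file.path(config$out_dir, "allelic.tsv"))
    results$allelic <- tested
    results$allelic_model <- model
    summary$allelic <- list(mu = model$mu, rho = model$rho,
                            n_snps = model$n_snps,
                            n_p05 = sum(tested$p < 0.05))
  }

  # --- stratified LD-score regression -----------------------------------
  if (isTRUE(config$stages$ldsc)) {
    lds <- compute_ld_scores(panel, annot)
    fit <- regress_partitioned(gwas$stats$chi2, lds, N = gw$N)
    enr <- enrichment_estimates(fit, lds)
    write_tsv_table(enr, file.path(config$out_dir, "enrichment.tsv"))
    results$enrichment <- enr
    summary$ldsc <- list(intercept = fit$intercept,
                         enrichment_focal = enr$enrichment[2],
                         conditional_p_focal = enr$conditional_p[2])
  }

  # --- permutation enrichment -------------------------------------------
  if (isTRUE(config$stages$permtest)) {
    if (is.null(results$atlas)) {
      stop("permtest stage requires the atlas stage output", call. = FALSE)
    }
    universe <- with_seed(seed + 8L, data.frame(
      snp = gwas$stats$snp,
      chrom = results$atlas$elements$chrom[1],
      pos = sample.int(max(results$atlas$elements$end), nrow(gwas$stats)),
      stringsAsFactors = FALSE
    ))
    risk <- universe$snp[gwas$stats$p < 1e-4]
    if (length(risk) < 2) {
      risk <- universe$snp[order(gwas$stats$p)[1:5]]
    }
    ot <- permutation_overlap_test(risk, universe, results$atlas$elements,
                                   n_perm = config$permtest$n_perm,
                                   seed = seed + 9L)
    results$permtest <- ot
    summary$permtest <- list(observed = ot$observed, p = ot$p,
                             n_perm = ot$n_perm)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, results = results))
}
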