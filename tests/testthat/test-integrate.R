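ap1_like_pwm <- function() {
  # near-deterministic consensus TGACTCA with a degenerate center
  cons <- c("T", "G", "A", "C", "T", "C", "A")
  mat <- matrix(0.01, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(cons)) mat[cons[i], i] <- 0.97
  pwm("AP1_like", mat, pseudocount = 0)
}

test_that("PWM scoring: consensus maximality, uniform neutrality, strands", {
  p <- ap1_like_pwm()
  cons_score <- pwm_score("TGACTCA", p)
  expect_gt(cons_score, 0)
  expect_equal(cons_score, 7 * log2(0.97 / 0.25), tolerance = 1e-9)

  # uniform motif scores 0 everywhere
  u <- pwm("uniform", matrix(0.25, 4, 5), pseudocount = 0)
  expect_equal(pwm_score("ACGTA", u), 0, tolerance = 1e-12)
  expect_equal(pwm_score("TTTTT", u), 0, tolerance = 1e-12)

  # exhaustive consensus maximality at L = 4
  m4 <- matrix(c(0.9, 0.04, 0.03, 0.03,
                 0.05, 0.8, 0.1, 0.05,
                 0.1, 0.1, 0.7, 0.1,
                 0.25, 0.25, 0.25, 0.25), nrow = 4)
  p4 <- pwm("toy4", m4, pseudocount = 0)
  best <- apply(p4$prob, 2, which.max)
  cons4 <- paste(c("A", "C", "G", "T")[best], collapse = "")
  all_seqs <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                                          stringsAsFactors = FALSE))
  scores <- vapply(all_seqs, function(s) pwm_score(s, p4), numeric(1))
  expect_equal(max(scores), pwm_score(cons4, p4), tolerance = 1e-12)

  # reverse-complement symmetry in both-strand mode
  expect_equal(pwm_score("TGACTCA", p, both_strands = TRUE),
               pwm_score("TGAGTCA", p, both_strands = TRUE),
               tolerance = 1e-12)

  expect_error(pwm_score("TGACTC", p), "length")
  expect_error(pwm_score("TGACTCN", p), "ambiguous")
})

test_that("allele delta equals the single-column log ratio", {
  p <- ap1_like_pwm()
  # risk allele destroys the final A of the consensus
  d <- pwm_delta_score("TGACTCA", "C", 7, p)
  expect_lt(d$delta, 0)
  expect_identical(d$prediction, "decreased")
  expect_equal(d$delta, unname(log2(p$prob["C", 7] / p$prob["A", 7])),
               tolerance = 1e-12)

  # column probabilities ref 0.97 vs alt 0.01: delta ~ -6.6
  expect_equal(log2(0.01 / 0.97), -6.6, tolerance = 0.01)

  # full-window rescoring equals the column delta on random PWMs
  set.seed(100)
  for (i in 1:25) {
    L <- sample(4:10, 1)
    mat <- matrix(rexp(4 * L), 4, L)
    pw <- pwm(sprintf("r%d", i), mat)
    seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    off <- sample.int(L, 1)
    ref_b <- substr(seq, off, off)
    alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
    d2 <- pwm_delta_score(seq, alt_b, off, pw)
    expect_equal(d2$delta,
                 unname(log2(pw$prob[alt_b, off] / pw$prob[ref_b, off])),
                 tolerance = 1e-9)
  }
  expect_error(pwm_delta_score("TGACTCA", "A", 7, p), "equals the reference")
})

test_that("the bundled synthetic AP-1-like motif loads and scores", {
  path <- system.file("extdata", "ap1_like.synthetic.jaspar",
                      package = "regelex")
  motifs <- read_jaspar(path)
  expect_identical(names(motifs), "AP1_like")
  expect_identical(motifs$AP1_like$length, 7L)
  expect_gt(pwm_score("TGACTCA", motifs$AP1_like), 0)
  expect_lt(pwm_delta_score("TGACTCA", "C", 7, motifs$AP1_like)$delta, 0)
})

test_that("JASPAR-style motif files round-trip", {
  tmp <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">M1 test_motif",
    "A [ 10  0  1 ]",
    "C [  0 12  1 ]",
    "G [  1  0 10 ]",
    "T [  1  0  0 ]"
  ), tmp)
  motifs <- read_jaspar(tmp)
  expect_length(motifs, 1)
  expect_identical(motifs$M1$length, 3L)
  expect_equal(colSums(motifs$M1$prob), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(motifs$M1$prob["C", 2]), 1, tolerance = 0.01)
})

test_that("gene-support classification applies the stated cutoffs", {
  diff_genes <- data.frame(
    gene = c("g_fdr20_both", "g_cand", "g_fdr10_none", "g_no_eqtl"),
    log2fc = c(1, 0.2, -2, 0),
    q = c(0.15, 0.8, 0.05, 0.9)
  )
  eqtls <- data.frame(
    gene = c("g_fdr20_both", "g_fdr20_both", "g_cand", "g_fdr10_none"),
    snp = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "chrS", pos = c(150L, 5000L, 150L, 9000L),
    p = 1e-8
  )
  gwas <- data.frame(snp = c("rs1", "rs3", "rs4"), p = c(1e-8, 1e-9, 0.5))
  diff_elements <- data.frame(id = "el1", chrom = "chrS", start = 100L,
                              end = 300L, p = 0.005)
  out <- classify_gene_support(diff_genes, eqtls, gwas, diff_elements)

  r1 <- out[out$gene == "g_fdr20_both", ]
  expect_identical(r1$tier, "fdr20")
  expect_true(r1$gwas_support && r1$atac_support)
  expect_false(r1$candidate)

  # not differential with both supports: flagged candidate
  r2 <- out[out$gene == "g_cand", ]
  expect_identical(r2$tier, "none")
  expect_true(r2$candidate)

  r3 <- out[out$gene == "g_fdr10_none", ]
  expect_identical(r3$tier, "fdr10")
  expect_false(r3$gwas_support || r3$atac_support)

  r4 <- out[out$gene == "g_no_eqtl", ]
  expect_false(r4$gwas_support || r4$atac_support)

  # Venn cells partition the gene list
  expect_identical(sum(table(out$category)), nrow(diff_genes))
})

test_that("pipeline runs end to end, deterministically, with stage gating", {
  cfg <- demo_config(seed = 7L, out_dir = withr::local_tempdir())
  cfg$panel <- list(n_individuals = 60L, n_blocks = 8L, snps_per_block = 15L,
                    n_founders_per_block = 4L, mutation_rate = 0.02)
  cfg$atac$n_elements <- 150L
  cfg$allelic$n_snps <- 60L
  cfg$atlas$n_elements <- 150L
  cfg$permtest$n_perm <- 200L
  res <- run_pipeline(cfg)
  expect_true(file.exists(file.path(cfg$out_dir, "summary.json")))
  expect_true(file.exists(file.path(cfg$out_dir, "credible_set.tsv")))
  expect_true(file.exists(file.path(cfg$out_dir, "differential.tsv")))
  for (stage in c("credible", "atlas", "diff", "allelic", "ldsc",
                  "permtest")) {
    expect_true(stage %in% names(res$summary), info = stage)
  }

  cfg2 <- cfg
  cfg2$out_dir <- withr::local_tempdir()
  res2 <- run_pipeline(cfg2)
  s1 <- res$summary; s2 <- res2$summary
  s1$parameters$out_dir <- s2$parameters$out_dir <- NULL
  expect_identical(s1, s2)

  # disabling a stage removes its outputs and summary fields
  cfg3 <- cfg
  cfg3$out_dir <- withr::local_tempdir()
  cfg3$stages$allelic <- FALSE
  res3 <- run_pipeline(cfg3)
  expect_false("allelic" %in% names(res3$summary))
  expect_false(file.exists(file.path(cfg3$out_dir, "allelic.tsv")))

  expect_error(run_pipeline(list(seed = 1)), "missing required")
})
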