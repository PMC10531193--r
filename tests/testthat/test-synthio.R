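test_that("haplotype panel is deterministic and drops monomorphic SNPs", {
  p1 <- simulate_haplotype_panel(50, 3, 10, 3, 0.02, seed = 1)
  p2 <- simulate_haplotype_panel(50, 3, 10, 3, 0.02, seed = 1)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$snp_meta, p2$snp_meta)
  p3 <- simulate_haplotype_panel(50, 3, 10, 3, 0.02, seed = 2)
  expect_false(identical(p1$haplotypes, p3$haplotypes))

  freq <- colMeans(p1$haplotypes)
  expect_true(all(freq > 0 & freq < 1))
  # positions strictly increasing, haplotype count even
  expect_true(all(diff(p1$snp_meta$pos) > 0))
  expect_identical(nrow(p1$haplotypes) %% 2L, 0L)

  expect_error(simulate_haplotype_panel(50, 3, 10, 3, 0.02),
               "seed")
  expect_error(simulate_haplotype_panel(1, 3, 10, 3, 0.02, seed = 1),
               "n_individuals")
  expect_error(simulate_haplotype_panel(50, 3, 10, 1, 0.02, seed = 1),
               "n_founders")
})

test_that("two-founder blocks are a single binary axis; blocks independent", {
  # mutation_rate 0, 2 founders: every retained SNP pair has r2 = 1
  p <- simulate_haplotype_panel(100, 1, 20, 2, 0, seed = 3)
  m <- ncol(p$haplotypes)
  expect_gt(m, 1)
  for (i in seq_len(min(m, 6))) {
    for (j in seq_len(min(m, 6))) {
      expect_equal(compute_r2(p, i, j), 1, tolerance = 1e-12)
    }
  }

  # cross-block r2 is near zero on average
  p2 <- simulate_haplotype_panel(500, 2, 20, 4, 0.02, seed = 4)
  b1 <- which(p2$snp_meta$block == 1)
  b2 <- which(p2$snp_meta$block == 2)
  r2s <- vapply(seq_len(200), function(i) {
    compute_r2(p2, sample(b1, 1), sample(b2, 1))
  }, numeric(1))
  expect_lt(mean(r2s), 0.05)
})

test_that("null GWAS z-scores have unit mean chi-squared", {
  panel <- simulate_haplotype_panel(200, 20, 25, 6, 0.05, seed = 5)
  chi2 <- vapply(1:5, function(s) {
    g <- simulate_gwas_summary(panel, tau = 0, N = 10000, seed = 10 + s)
    mean(g$stats$chi2)
  }, numeric(1))
  expect_gt(mean(chi2), 0.9)
  expect_lt(mean(chi2), 1.1)

  # N = 0: no-signal limit, same null behavior
  g0 <- simulate_gwas_summary(panel, tau = 0, N = 0, seed = 16)
  expect_gt(mean(g0$stats$chi2), 0.85)
  expect_lt(mean(g0$stats$chi2), 1.15)
  expect_true(all(is.na(g0$stats$beta_hat)))
})

test_that("negative per-SNP variance is rejected with offending SNPs named", {
  panel <- small_panel()
  m <- ncol(panel$haplotypes)
  a <- matrix(1, m, 1)
  expect_error(simulate_gwas_summary(panel, a, tau = -1e-4, N = 100, seed = 1),
               "negative per-SNP variance")
})

test_that("ATAC counts: truth bookkeeping, Poisson limit, determinism", {
  s0 <- simulate_atac_counts(200, c(3L, 3L), spike_fraction = 0, seed = 7)
  expect_identical(sum(s0$truth$spiked), 0L)
  expect_true(all(s0$truth$log2fc == 0))

  s1 <- simulate_atac_counts(200, c(3L, 3L), spike_fraction = 0.1,
                             spike_log2fc = 2, seed = 7)
  expect_identical(sum(s1$truth$spiked), 20L)
  expect_identical(
    s1$counts, simulate_atac_counts(200, c(3L, 3L), spike_fraction = 0.1,
                                    spike_log2fc = 2, seed = 7)$counts)

  # NB -> Poisson: tiny dispersion, many replicates, variance ~ mean
  sp <- simulate_atac_counts(300, c(100L, 100L), dispersion = 1e-6,
                             baseline_logmean_range = c(6, 6),
                             spike_fraction = 0, seed = 8)
  sf <- sp$size_factors
  norm <- sweep(sp$counts, 2, sf, "/")
  ratio <- apply(norm, 1, var) / rowMeans(norm)
  expect_equal(median(ratio), 1, tolerance = 0.15)

  expect_error(simulate_atac_counts(10, c(0L, 3L), seed = 1), "group_sizes")
})

test_that("allelic counts follow the beta-binomial variance law", {
  # rho = 0, theta = 0.5: per-SNP het fraction variance ~ binomial
  s <- simulate_allele_counts(2000, 1, depth_mean = 40, theta = 0.5,
                              rho = 0, het_rate = 1, seed = 9)
  het <- s$table[s$table$ref_reads + s$table$alt_reads > 0, ]
  f <- het$ref_reads / (het$ref_reads + het$alt_reads)
  d <- het$ref_reads + het$alt_reads
  expect_equal(var(f), mean(0.25 / d), tolerance = 0.15)

  # rho = 0.3: variance exceeds binomial by ~ 1 + (depth - 1) rho
  s2 <- simulate_allele_counts(3000, 1, depth_mean = 50, theta = 0.5,
                               rho = 0.3, het_rate = 1, seed = 10)
  het2 <- s2$table[s2$table$ref_reads + s2$table$alt_reads > 0, ]
  d2 <- het2$ref_reads + het2$alt_reads
  f2 <- het2$ref_reads / d2
  factor_obs <- var(f2) / mean(0.25 / d2)
  expect_equal(factor_obs, 1 + (mean(d2) - 1) * 0.3, tolerance = 0.1 *
                 (1 + (mean(d2) - 1) * 0.3))

  # truth records per-SNP theta
  theta <- rep(0.5, 50); theta[1:5] <- 0.6
  s3 <- simulate_allele_counts(50, 5, theta = theta, seed = 11)
  expect_equal(s3$truth$theta[1:5], rep(0.6, 5))
  expect_equal(s3$truth$theta[6:50], rep(0.5, 45))
  expect_error(simulate_allele_counts(10, 5, rho = 1, seed = 1), "rho")
})

test_that("element atlas hits its target active fraction", {
  a1 <- simulate_element_atlas(200, c("x", "y"), active_fraction = 1, seed = 12)
  expect_true(all(a1$zscores > 1.64))

  a <- simulate_element_atlas(10000, c("x", "y", "z"), active_fraction = 0.3,
                              seed = 13)
  expect_true(all(a$elements$start < a$elements$end))
  expect_true(all(diff(a$elements$start) > 0))
  expect_true(all(utils::head(a$elements$end, -1) <=
                    utils::tail(a$elements$start, -1)))
  emp <- mean(a$zscores > 1.64)
  expect_lt(abs(emp - 0.3), 0.05)
})

test_that("fixture round-trips are lossless", {
  tmp <- withr::local_tempdir()
  panel <- small_panel()
  write_panel(panel, file.path(tmp, "panel"))
  back <- read_panel(file.path(tmp, "panel"))
  expect_equal(unname(back$haplotypes), unname(panel$haplotypes))
  expect_equal(back$snp_meta$snp, panel$snp_meta$snp)
  expect_equal(back$snp_meta$pos, panel$snp_meta$pos)

  atlas <- simulate_element_atlas(20, c("b1", "b2"), 0.5, seed = 14)
  write_atlas(atlas, file.path(tmp, "atlas"))
  back2 <- read_atlas(file.path(tmp, "atlas"))
  expect_equal(back2$elements, atlas$elements)
  expect_equal(back2$zscores, atlas$zscores, tolerance = 1e-10)

  df <- data.frame(a = 1:3, b = c("x", "y", "z"), stringsAsFactors = FALSE)
  write_tsv_table(df, file.path(tmp, "t.tsv"))
  expect_equal(read_tsv_table(file.path(tmp, "t.tsv")), df)
})
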