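test_that("loess offsets vanish for identical samples and capture scaling", {
  set.seed(40)
  base <- matrix(rnbinom(1000 * 3, mu = rep(2^runif(1000, 4, 9), 3),
                         size = 1e6), ncol = 3)
  same <- cbind(base[, 1], base[, 1], base[, 1], base[, 1])
  offs <- loess_normalize(same)
  expect_lt(max(abs(offs)), 1e-6)

  # a x2-scaled sample shows up as a ~ +1 log2 offset (30 samples)
  S <- 30
  mu <- 2^runif(1500, 4, 9)
  counts <- matrix(rnbinom(1500 * S, mu = rep(mu, S), size = 10), ncol = S)
  counts[, 1] <- rnbinom(1500, mu = 2 * mu, size = 10)
  offs2 <- loess_normalize(counts)
  expect_lt(abs(mean(offs2[, 1]) - 1), 0.05)
  expect_lt(max(abs(rowSums(offs2))), 1e-8)

  # abundance-dependent bias (M = 0.5 A added to one sample) is removed
  lc <- log2(counts[, -1] + 0.5)
  A <- rowMeans(lc)
  biased <- counts[, -1]
  biased[, 1] <- round(biased[, 1] * 2^(0.5 * A))
  offs3 <- loess_normalize(biased)
  resid <- (log2(biased[, 1] + 0.5) - rowMeans(log2(biased + 0.5))) -
    offs3[, 1]
  slope <- coef(lm(resid ~ rowMeans(log2(biased + 0.5))))[2]
  expect_lt(abs(slope), 0.05)

  expect_error(loess_normalize(matrix(0, 5, 3)), "all-zero")
})

test_that("NB LRT is calibrated under the null and finds strong spikes", {
  sim <- simulate_atac_counts(800, c(10L, 11L), dispersion = 0.1,
                              spike_fraction = 0, seed = 41)
  res <- test_differential(sim$counts, loess_normalize(sim$counts),
                           sim$groups)
  expect_gt(mean(res$p < 0.05, na.rm = TRUE), 0.02)
  expect_lt(mean(res$p < 0.05, na.rm = TRUE), 0.08)

  # 4-fold spikes at means bracketing 200, dispersion 0.1, 10 vs 11
  # samples: recovered at q < 0.05
  sim2 <- simulate_atac_counts(400, c(10L, 11L), dispersion = 0.1,
                               baseline_logmean_range = c(6, 9),
                               spike_fraction = 0.05, spike_log2fc = 2,
                               seed = 42)
  res2 <- test_differential(sim2$counts, loess_normalize(sim2$counts),
                            sim2$groups)
  spiked <- res2$element %in% sim2$truth$element[sim2$truth$spiked]
  expect_gte(mean(res2$q[spiked] < 0.05), 0.85)
  # away from the abundance extremes (where the loess trend is estimated
  # from a spike-dominated neighborhood) every spike is recovered
  interior <- spiked & res2$A < 9
  expect_true(all(res2$q[interior] < 0.05))
  expect_gt(mean(res2$log2fc[interior]), 1.5)

  # all-zero elements are excluded but reported
  counts <- sim$counts
  counts[1, ] <- 0L
  res3 <- test_differential(counts, NULL, sim$groups)
  expect_false(res3$tested[1])
  expect_true(is.na(res3$p[1]))
  expect_true(all(res3$tested[-1]))

  expect_error(test_differential(sim$counts, NULL,
                                 rep(c("a", "b"), c(1, 20))),
               "at least 2 samples")
})

test_that("swapping group labels negates log2FC and preserves p", {
  sim <- simulate_atac_counts(150, c(4L, 5L), spike_fraction = 0.1,
                              seed = 43)
  offs <- loess_normalize(sim$counts)
  fwd <- test_differential(sim$counts, offs, sim$groups)
  swapped <- factor(ifelse(sim$groups == "g1", "g2", "g1"),
                    levels = c("g1", "g2"))
  rev <- test_differential(sim$counts, offs, swapped)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-9)
  expect_equal(fwd$p, rev$p, tolerance = 1e-9)
  # BH is a monotone transform with q >= p
  expect_true(all(fwd$q >= fwd$p - 1e-12, na.rm = TRUE))
  ord <- order(fwd$p)
  expect_true(all(diff(fwd$q[ord][!is.na(fwd$q[ord])]) >= -1e-12))
})

test_that("KS shift test agrees with a textbook implementation", {
  x <- c(1, 2, 3)
  expect_equal(ks_shift_test(x, x), list(D = 0, p = 1))
  expect_equal(ks_shift_test(1:5, 11:15)$D, 1)

  set.seed(44)
  q <- rnorm(500)
  b <- rnorm(2000, 0.2)
  got <- ks_shift_test(q, b)
  want <- ks_oracle(q, b)
  expect_equal(got$D, want$D, tolerance = 1e-6)
  expect_equal(got$p, want$p, tolerance = 0.1 * want$p)
  expect_error(ks_shift_test(numeric(0), 1:3), "nonempty")
})

test_that("motif enrichment matches the hypergeometric oracle", {
  diff_el <- sprintf("d%03d", 1:100)
  bg_el <- sprintf("b%03d", 1:100)
  hits <- c(
    setNames(lapply(1:30, function(i) "M1"), diff_el[1:30]),
    setNames(lapply(1:10, function(i) "M1"), bg_el[1:10]),
    setNames(lapply(1:20, function(i) "M2"), diff_el[41:60]),
    setNames(lapply(1:20, function(i) "M2"), bg_el[41:60])
  )
  hits <- tapply(unlist(hits), rep(names(hits), lengths(hits)), c,
                 simplify = FALSE)
  res <- motif_enrichment(diff_el, bg_el, hits)
  m1 <- res[res$motif == "M1", ]
  expect_equal(m1$or, (30 * 90) / (70 * 10), tolerance = 1e-12)

  # exact two-sided p by enumerating the hypergeometric tables
  pmf <- dhyper(0:40, 100, 100, 40)
  p_oracle <- sum(pmf[pmf <= pmf[31] * (1 + 1e-7)])
  expect_equal(m1$p, p_oracle, tolerance = 1e-9)

  m2 <- res[res$motif == "M2", ]
  expect_equal(m2$or, 1)
  expect_gt(m2$p, 0.99)

  # zero background cell: OR infinite, p still finite
  hits2 <- setNames(lapply(1:5, function(i) "M3"), diff_el[1:5])
  res2 <- motif_enrichment(diff_el, bg_el, hits2)
  expect_identical(res2$or[res2$motif == "M3"], Inf)
  expect_lt(res2$p[res2$motif == "M3"], 1)

  expect_error(motif_enrichment(c("a", "b"), c("b", "c"), list()),
               "disjoint")
})

test_that("chromatin-state calls and transition marginals are conserved", {
  pre <- cbind(H3K27ac = c(2.0, 0.1, 0.1), H3K4me1 = c(2.0, 2.0, 0.3))
  post <- cbind(H3K27ac = c(2.0, 2.0, 0.1), H3K4me1 = c(2.0, 2.0, 0.2))
  rownames(pre) <- rownames(post) <- c("e1", "e2", "e3")
  st <- state_transitions(pre, post)
  expect_identical(st$states$state_pre, c("active", "poised", "inactive"))
  expect_identical(st$states$state_post, c("active", "active", "inactive"))
  expect_identical(unname(st$transitions["poised", "active"]), 1L)
  expect_equal(as.vector(rowSums(st$transitions)),
               as.vector(table(factor(st$states$state_pre,
                                      levels = c("inactive", "poised",
                                                 "active")))))
  expect_error(state_transitions(pre[, 1, drop = FALSE], post),
               "missing mark")
})
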