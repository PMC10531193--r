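# Differential chromatin accessibility on element count matrices:
# loess MA-trend normalization, a negative-binomial likelihood-ratio test
# with empirical-Bayes-shrunk dispersions, and the downstream readouts
# (distribution-shift KS test, motif enrichment, chromatin-state
# transitions).

#' Loess MA-trend normalization offsets
#'
#' For each sample, fits a loess curve of M (that sample's log2 count minus
#' the across-sample mean log2 count for the element, i.e. log2 of the
#' sample/geometric-mean ratio at a common library size) against A (mean
#' log2 abundance), and returns the fitted trend as a per-element,
#' per-sample offset. Offsets absorb both library-size differences and
#' abundance-dependent (trended) biases, and are centered so that each
#' element's offsets sum to zero across samples.
#'
#' @param counts element x sample matrix of non-negative counts.
#' @param span loess span (default 0.3).
#' @param prior_count pseudocount added before taking log2 (default 0.5).
#' @return offset matrix (log2 scale) with the same dimensions as `counts`;
#'   attribute `"A"` holds the per-element mean log2 abundance.
#' @export
loess_normalize <- function(counts, span = 0.3, prior_count = 0.5) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count matrix", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  lc <- log2(counts + prior_count)
  A <- rowMeans(lc)
  offsets <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (s in seq_len(ncol(counts))) {
    M <- lc[, s] - A
    if (stats::sd(M) < 1e-10) {
      # degenerate: constant M (e.g. identical samples); trend is the
      # constant itself
      offsets[, s] <- M
    } else {
      # robust (symmetric) fitting so a minority of truly differential
      # elements does not bend the trend
      fit <- loess(M ~ A, span = span, degree = 1, family = "symmetric",
                   control = stats::loess.control(surface = "direct"))
      offsets[, s] <- fit$fitted
    }
  }
  offsets <- offsets - rowMeans(offsets)
  structure(offsets, A = A)
}

# NB log-likelihood pieces. size = 1/dispersion; terms constant in mu are
# kept so likelihood ratios across nested mean models are exact.
nb_loglik <- function(y, mu, size) {
  stats::dnbinom(y, mu = pmax(mu, 1e-12), size = size, log = TRUE)
}

# Newton solve for the scalar log-mean `a` of one group of one element:
# mu_s = exp(a + t_s). Vectorized over elements: y, t are n_e x n_s
# matrices, returns the per-element `a` (log scale).
nb_fit_logmean <- function(y, t, size, n_iter = 25L) {
  et <- exp(t)
  ybar <- rowSums(y)
  a <- log((ybar + 0.125) / rowSums(et))
  for (it in seq_len(n_iter)) {
    mu <- exp(a) * et
    w <- (y + size) * mu / (mu + size)
    grad <- ybar - rowSums(w)
    hess <- rowSums(w * size / (mu + size))
    step <- grad / pmax(hess, 1e-10)
    step <- pmax(pmin(step, 3), -3)
    a <- a + step
    if (max(abs(step)) < 1e-10) break
  }
  a
}

# Profile (Cox-Reid adjusted) log-likelihood of the full two-group model at
# dispersion phi, summed over samples, per element. y/t: n_e x n_s.
nb_profile_ll <- function(y, t, groups, phi, adjust = TRUE) {
  size <- 1 / phi
  ll <- numeric(nrow(y))
  for (g in levels(groups)) {
    cols <- which(groups == g)
    yg <- y[, cols, drop = FALSE]
    tg <- t[, cols, drop = FALSE]
    a <- nb_fit_logmean(yg, tg, size)
    mu <- exp(a) * exp(tg)
    ll_g <- rowSums(nb_loglik(yg, mu, size))
    if (adjust) {
      info <- rowSums((yg + size) * mu * size / (mu + size)^2)
      ll_g <- ll_g - 0.5 * log(pmax(info, 1e-10))
    }
    ll <- ll + ll_g
  }
  ll
}

#' Negative-binomial likelihood-ratio test for a two-group design
#'
#' Per element, tests the group effect with the normalization offsets held
#' fixed: a likelihood-ratio test of the two-mean NB model against the
#' one-mean null, with the dispersion estimated by Cox-Reid-adjusted maximum
#' likelihood -- a global value across elements, per-element values shrunk
#' toward it on the log scale with `prior_df` prior degrees of freedom.
#' All-zero elements are excluded from testing and reported with
#' `tested = FALSE`. Benjamini-Hochberg correction is applied across tested
#' elements.
#'
#' @param counts element x sample count matrix.
#' @param offsets log2-scale offset matrix from [loess_normalize()] (NULL
#'   for none).
#' @param groups factor of two condition labels, each with >= 2 samples.
#' @param prior_df prior degrees of freedom for dispersion shrinkage
#'   (default 20).
#' @return data.frame (class `DiffResult`): element, A, log2fc, dispersion,
#'   p, q, tested.
#' @export
test_differential <- function(counts, offsets = NULL, groups, prior_df = 20) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("'groups' must have exactly two levels",
                                  call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (is.null(offsets)) offsets <- matrix(0, nrow(counts), ncol(counts))
  t_nat <- offsets * log(2)

  tested <- rowSums(counts) > 0
  y <- counts[tested, , drop = FALSE]
  t <- t_nat[tested, , drop = FALSE]

  # global dispersion: maximize the summed CR-adjusted profile likelihood
  opt <- optimize(
    function(lphi) sum(nb_profile_ll(y, t, groups, exp(lphi))),
    interval = log(c(1e-4, 5)), maximum = TRUE, tol = 1e-3
  )
  phi_global <- exp(opt$maximum)

  # per-element dispersion on a log grid, then shrink toward the global
  grid <- seq(log(1e-4), log(5), length.out = 31L)
  ll_grid <- vapply(grid, function(lphi)
    nb_profile_ll(y, t, groups, exp(lphi)), numeric(nrow(y)))
  lphi_e <- grid[max.col(ll_grid, ties.method = "first")]
  df_e <- ncol(y) - 2L
  lphi_shrunk <- (prior_df * log(phi_global) + df_e * lphi_e) /
    (prior_df + df_e)
  phi <- exp(lphi_shrunk)

  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  n_e <- nrow(y)
  ll_full <- ll_null <- numeric(n_e)
  a1 <- a2 <- numeric(n_e)
  # dispersions differ per element; bucket by unique value for vectorization
  for (ph in unique(phi)) {
    idx <- which(phi == ph)
    size <- 1 / ph
    yi <- y[idx, , drop = FALSE]
    ti <- t[idx, , drop = FALSE]
    a1[idx] <- nb_fit_logmean(yi[, g1, drop = FALSE], ti[, g1, drop = FALSE], size)
    a2[idx] <- nb_fit_logmean(yi[, g2, drop = FALSE], ti[, g2, drop = FALSE], size)
    a0 <- nb_fit_logmean(yi, ti, size)
    mu_full <- cbind(exp(a1[idx]) * exp(ti[, g1, drop = FALSE]),
                     exp(a2[idx]) * exp(ti[, g2, drop = FALSE]))
    mu_full <- mu_full[, order(c(g1, g2)), drop = FALSE]
    ll_full[idx] <- rowSums(nb_loglik(yi, mu_full, size))
    ll_null[idx] <- rowSums(nb_loglik(yi, exp(a0) * exp(ti), size))
  }
  lrt <- pmax(2 * (ll_full - ll_null), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  res <- data.frame(
    element = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    A = rowMeans(log2(counts + 0.5)),
    log2fc = NA_real_, dispersion = NA_real_,
    p = NA_real_, q = NA_real_, tested = tested,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$log2fc[tested] <- (a2 - a1) / log(2)
  res$dispersion[tested] <- phi
  res$p[tested] <- p
  res$q[tested] <- p.adjust(p, method = "BH")
  class(res) <- c("DiffResult", class(res))
  res
}

#' Two-sample Kolmogorov-Smirnov shift test
#'
#' Compares the distribution of a query set of values (e.g. stimulation
#' log2 fold changes of patient-responsive elements) against a background
#' set: D is the supremum distance between the two empirical CDFs with the
#' asymptotic two-sided p-value.
#'
#' @param query_values,background_values numeric vectors (nonempty).
#' @return list with `D` and `p`.
#' @export
ks_shift_test <- function(query_values, background_values) {
  if (length(query_values) == 0L || length(background_values) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  kt <- suppressWarnings(
    ks.test(query_values, background_values, alternative = "two.sided",
            exact = FALSE)
  )
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Motif enrichment in differential versus background elements
#'
#' Per motif, a Fisher exact test on the 2x2 table of
#' (has motif / lacks motif) x (differential / background), with the sample
#' odds ratio `(a d)/(b c)` reported (Inf for a zero cell) and BH correction
#' across motifs present in at least one set. Motifs absent from both sets
#' are reported with `or = NA` and excluded from the BH correction.
#'
#' @param diff_elements,background_elements disjoint character vectors of
#'   element ids.
#' @param motif_hits named list: element id -> character vector of motif ids
#'   hitting that element.
#' @return data.frame: motif, n_diff, n_bg, or, log2_or, p, q.
#' @export
motif_enrichment <- function(diff_elements, background_elements, motif_hits) {
  if (length(intersect(diff_elements, background_elements)) > 0L) {
    stop("differential and background element sets must be disjoint",
         call. = FALSE)
  }
  motifs <- sort(unique(unlist(motif_hits)))
  n_d <- length(diff_elements)
  n_b <- length(background_elements)
  has_motif <- function(els, m) {
    sum(vapply(els, function(e) m %in% (motif_hits[[e]] %||% character(0)),
               logical(1)))
  }
  rows <- lapply(motifs, function(m) {
    a <- has_motif(diff_elements, m)
    c_ <- has_motif(background_elements, m)
    b <- n_d - a
    d <- n_b - c_
    if (a + c_ == 0L) {
      return(data.frame(motif = m, n_diff = a, n_bg = c_, or = NA_real_,
                        log2_or = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    or <- (a * d) / (b * c_)
    p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
    data.frame(motif = m, n_diff = a, n_bg = c_, or = or,
               log2_or = log2(or), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out
}

#' Chromatin-state calls and transitions between two conditions
#'
#' Per element, the state is `active` if the active-enhancer mark (e.g.
#' H3K27ac) exceeds `z_cut`, else `poised` if the priming mark (e.g.
#' H3K4me1) exceeds `z_cut`, else `inactive`. The transition table
#' cross-tabulates pre- versus post-condition states; its row sums equal
#' the pre-condition state counts.
#'
#' @param pre_marks,post_marks element x mark matrices of normalized mark
#'   signal with named columns.
#' @param active_mark,poised_mark column names of the two marks.
#' @param z_cut state-call threshold (default 1.64).
#' @return list with `states` (data.frame: element, state_pre, state_post)
#'   and `transitions` (pre x post contingency table).
#' @export
state_transitions <- function(pre_marks, post_marks,
                              active_mark = "H3K27ac",
                              poised_mark = "H3K4me1", z_cut = 1.64) {
  lv <- c("inactive", "poised", "active")
  call_states <- function(m) {
    for (mk in c(active_mark, poised_mark)) {
      if (!mk %in% colnames(m)) {
        stop(sprintf("missing mark column '%s'", mk), call. = FALSE)
      }
    }
    factor(ifelse(m[, active_mark] > z_cut, "active",
                  ifelse(m[, poised_mark] > z_cut, "poised", "inactive")),
           levels = lv)
  }
  s_pre <- call_states(pre_marks)
  s_post <- call_states(post_marks)
  list(
    states = data.frame(
      element = rownames(pre_marks) %||% as.character(seq_along(s_pre)),
      state_pre = as.character(s_pre),
      state_post = as.character(s_post),
      stringsAsFactors = FALSE
    ),
    transitions = table(pre = s_pre, post = s_post)
  )
}
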