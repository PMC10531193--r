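# Element-atlas operations: activity calling on Z-score matrices,
# variant/element intersection, TCR-response set algebra, and per-locus
# TCR-response classification.

#' Call active elements from a Z-score matrix
#'
#' An element is active iff its activity Z-score strictly exceeds `z_cut` in
#' at least `min_datasets` columns. The default Z > 1.64 (one-sided 5%
#' normal quantile) in >= 3 datasets mirrors standard atlas activity calls;
#' the inequality is strict, so Z exactly at the cut does not count.
#'
#' @param zscores element x dataset numeric matrix with element row names.
#' @param z_cut activity threshold (default 1.64).
#' @param min_datasets minimum number of datasets exceeding the cut.
#' @return character vector of active element ids.
#' @export
threshold_active_elements <- function(zscores, z_cut = 1.64, min_datasets = 3L) {
  if (is.null(dim(zscores)) || nrow(zscores) == 0L || ncol(zscores) == 0L) {
    stop("'zscores' must be a non-empty matrix", call. = FALSE)
  }
  min_datasets <- assert_count(min_datasets, "min_datasets")
  n_exceed <- rowSums(zscores > z_cut)
  rownames(zscores)[n_exceed >= min_datasets] %||%
    as.character(which(n_exceed >= min_datasets))
}

#' Select the top-k most active elements
#'
#' The k elements with the largest signal; ties at the boundary broken by
#' element id ascending. If `k >= length(signal)` all elements are returned.
#'
#' @param signal named numeric vector of per-element activity.
#' @param k number of elements to keep.
#' @return character vector of selected element ids.
#' @export
select_top_k_elements <- function(signal, k) {
  k <- assert_count(k, "k")
  ids <- names(signal) %||% as.character(seq_along(signal))
  ord <- order(-signal, ids)
  ids[ord][seq_len(min(k, length(signal)))]
}

#' Intersect variant positions with element intervals
#'
#' Variants are 1-based; elements are 0-based half-open. A variant at
#' position p hits [s, e) iff s <= p - 1 < e. Overlap is computed with
#' GenomicRanges; a brute-force scan gives identical results (tested).
#'
#' @param variants data.frame with snp, chrom, pos (1-based).
#' @param elements data.frame with id, chrom, start, end (0-based
#'   half-open).
#' @return named list, one entry per variant (in input order), each a sorted
#'   character vector of overlapping element ids.
#' @export
intersect_variants_elements <- function(variants, elements) {
  validate_intervals(elements$start, elements$end)
  out <- setNames(vector("list", nrow(variants)), variants$snp)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (NROW(elements) == 0L || NROW(variants) == 0L) return(out)
  vgr <- granges_from_positions(variants$chrom, variants$pos)
  egr <- granges_from_bed(elements$chrom, elements$start, elements$end,
                          id = elements$id)
  ov <- GenomicRanges::findOverlaps(vgr, egr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  for (i in unique(qh)) {
    out[[i]] <- sort(elements$id[sh[qh == i]])
  }
  out
}

#' TCR-response set algebra across T-cell lineages
#'
#' From a per-lineage differential table, an element is "up" in a lineage if
#' `q < q_cut` and `log2fc > 0` (and "down" symmetrically). Up/down unions
#' are taken within the CD4 and CD8 lineage groups; `shared_cd4_cd8` holds
#' elements responsive (either direction) in both groups, `cd4_only` /
#' `cd8_only` those responsive in exactly one, and `discordant` elements up
#' in at least one lineage and down in at least one other.
#'
#' @param per_lineage_diff data.frame with element, lineage, log2fc, q.
#' @param lineage_groups named character vector mapping lineage ->
#'   "CD4"/"CD8".
#' @param q_cut FDR cut for calling a lineage response (default 0.05).
#' @return list of character vectors: up_union, down_union, responsive,
#'   shared_cd4_cd8, cd4_only, cd8_only, discordant.
#' @export
tcr_response_sets <- function(per_lineage_diff, lineage_groups, q_cut = 0.05) {
  lins <- unique(per_lineage_diff$lineage)
  unknown <- setdiff(lins, names(lineage_groups))
  if (length(unknown) > 0) {
    stop(sprintf("unknown lineage group for: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sig <- per_lineage_diff$q < q_cut
  up <- per_lineage_diff[sig & per_lineage_diff$log2fc > 0, , drop = FALSE]
  dn <- per_lineage_diff[sig & per_lineage_diff$log2fc < 0, , drop = FALSE]
  group_of <- function(df) lineage_groups[df$lineage]
  resp_by_group <- function(g) {
    union(unique(up$element[group_of(up) == g]),
          unique(dn$element[group_of(dn) == g]))
  }
  cd4 <- resp_by_group("CD4")
  cd8 <- resp_by_group("CD8")
  list(
    up_union = sort(unique(up$element)),
    down_union = sort(unique(dn$element)),
    responsive = sort(union(unique(up$element), unique(dn$element))),
    shared_cd4_cd8 = sort(intersect(cd4, cd8)),
    cd4_only = sort(setdiff(cd4, cd8)),
    cd8_only = sort(setdiff(cd8, cd4)),
    discordant = sort(intersect(unique(up$element), unique(dn$element)))
  )
}

#' Classify a locus by the TCR response of the elements its variants hit
#'
#' @param locus_variants data.frame with snp, chrom, pos (1-based).
#' @param atlas an `ElementAtlas` (or data.frame of elements).
#' @param tcell_element_ids element ids active in T cells.
#' @param up_ids,down_ids TCR-upregulated / downregulated element ids
#'   (subsets of `tcell_element_ids`).
#' @return one of "up_only", "down_only", "both", "tcell_nonresponsive",
#'   "no_tcell_element".
#' @export
classify_locus_tcr <- function(locus_variants, atlas, tcell_element_ids,
                               up_ids, down_ids) {
  if (!all(up_ids %in% tcell_element_ids) ||
      !all(down_ids %in% tcell_element_ids)) {
    stop("up/down ids must be subsets of the T-cell element ids",
         call. = FALSE)
  }
  elements <- if (inherits(atlas, "ElementAtlas")) atlas$elements else atlas
  hits <- unique(unlist(intersect_variants_elements(locus_variants, elements)))
  t_hits <- intersect(hits, tcell_element_ids)
  if (length(t_hits) == 0L) return("no_tcell_element")
  has_up <- length(intersect(t_hits, up_ids)) > 0L
  has_dn <- length(intersect(t_hits, down_ids)) > 0L
  if (has_up && has_dn) "both"
  else if (has_up) "up_only"
  else if (has_dn) "down_only"
  else "tcell_nonresponsive"
}
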