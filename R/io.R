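# Plain-text fixture formats: BED6 (0-based half-open), TSV tables with a
# single '#'-prefixed header line, and a VCF-like variant table (1-based
# positions, REF/ALT columns) with a binary haplotype-matrix sidecar.
# Round-trips are lossless.

#' Write intervals as BED6
#'
#' @param df data.frame with chrom, start, end (0-based half-open), id, and
#'   optionally score and strand.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df$start, df$end)
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = df$id %||% ".",
    score = df$score %||% 0,
    strand = df$strand %||% "."
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into a data.frame of 0-based half-open intervals
#' @param path BED file path.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[seq_len(min(6L, ncol(df)))] <-
    c("chrom", "start", "end", "id", "score", "strand")[seq_len(min(6L, ncol(df)))]
  validate_intervals(df$start, df$end)
  df
}

#' Write a data.frame as TSV with a '#'-prefixed header line
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#' @param path input path.
#' @export
read_tsv_table <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- read.delim(path, header = FALSE, skip = 1L, stringsAsFactors = FALSE)
  names(df) <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df
}

#' Write a haplotype panel as a VCF-like variant table plus matrix sidecar
#'
#' The variant table (`<prefix>.variants.tsv`) has 1-based positions and
#' REF/ALT columns; the sidecar (`<prefix>.haplotypes.tsv`) holds the binary
#' haplotype matrix, one row per haplotype.
#'
#' @param panel a `HaplotypePanel`.
#' @param prefix path prefix for the two files.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  write_tsv_table(panel$snp_meta, paste0(prefix, ".variants.tsv"))
  write.table(panel$haplotypes, paste0(prefix, ".haplotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a haplotype panel written by [write_panel()]
#' @param prefix path prefix used at write time.
#' @export
read_panel <- function(prefix) {
  meta <- read_tsv_table(paste0(prefix, ".variants.tsv"))
  haps <- as.matrix(read.delim(paste0(prefix, ".haplotypes.tsv"),
                               header = FALSE))
  dimnames(haps) <- list(NULL, meta$snp)
  storage.mode(haps) <- "integer"
  panel <- list(haplotypes = haps, snp_meta = meta)
  class(panel) <- "HaplotypePanel"
  panel
}

#' Write an element atlas as BED6 plus a Z-score TSV keyed by element id
#' @param atlas an `ElementAtlas`.
#' @param prefix path prefix for the two files.
#' @export
write_atlas <- function(atlas, prefix) {
  stopifnot(inherits(atlas, "ElementAtlas"))
  write_bed(atlas$elements, paste0(prefix, ".elements.bed"))
  zdf <- data.frame(id = rownames(atlas$zscores), atlas$zscores,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(zdf, paste0(prefix, ".zscores.tsv"))
  invisible(prefix)
}

#' Read an element atlas written by [write_atlas()]
#' @param prefix path prefix used at write time.
#' @export
read_atlas <- function(prefix) {
  el <- read_bed(paste0(prefix, ".elements.bed"))
  zdf <- read_tsv_table(paste0(prefix, ".zscores.tsv"))
  z <- as.matrix(zdf[, -1, drop = FALSE])
  rownames(z) <- zdf$id
  atlas <- list(
    elements = data.frame(id = el$id, chrom = el$chrom, start = el$start,
                          end = el$end, stringsAsFactors = FALSE),
    zscores = z
  )
  class(atlas) <- "ElementAtlas"
  atlas
}
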