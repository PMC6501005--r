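#' Genome model: ordered chromosomes with lengths
#'
#' @param chrom character vector of unique chromosome names.
#' @param length_bp integer-ish vector of chromosome lengths (> 0 bp).
#'
#' @return a `genome_model` data.frame with columns `chrom`, `length_bp`.
#' @export
#'
#' @examples
#' genome_model(c("chr1", "chr2"), c(2.5e6, 1e6))
genome_model <- function(chrom, length_bp) {
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  if (length(chrom) == 0L) stopf("genome must have at least one chromosome")
  if (length(chrom) != length(length_bp))
    stopf("chrom and length_bp must have equal length")
  if (anyDuplicated(chrom)) stopf("chromosome names must be unique")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stopf("chromosome lengths must be positive")
  g <- data.frame(chrom = chrom, length_bp = length_bp,
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_model", "data.frame")
  g
}

#' Read a chrom.sizes file (chrom<TAB>length)
#' @param path path to a two-column tab-separated file, no header.
#' @return a [genome_model()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stopf("chrom.sizes file not found: '%s'", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length_bp"),
                          stringsAsFactors = FALSE)
  genome_model(df$chrom, df$length_bp)
}

#' Write a genome as chrom.sizes
#' @param genome a [genome_model()].
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(
      data.frame(genome$chrom, format(genome$length_bp, scientific = FALSE, trim = TRUE)),
      tmp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  })
}
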