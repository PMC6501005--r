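#' Peak set: genomic intervals for one factor
#'
#' Coordinates are 0-based, half-open (BED convention) throughout the
#' package. Intervals are sorted by (chrom, start, end) on construction.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds, `start < end`.
#' @param name optional factor name (e.g. the ChIPed protein), stored as an
#'   attribute.
#' @param score optional numeric score per interval.
#'
#' @return a `peak_set` data.frame with columns `chrom`, `start`, `end` (and
#'   `score` if given).
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end))
    stopf("chrom, start, end must have equal length")
  if (any(start < 0)) stopf("starts must be >= 0 (0-based half-open)")
  if (any(start >= end)) stopf("all intervals must satisfy start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "factor_name") <- name
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Check a peak set against a genome
#'
#' @param peaks a [peak_set()].
#' @param genome a [genome_model()].
#' @return `peaks`, invisibly; errors list offending chromosomes or
#'   out-of-bounds intervals.
#' @export
validate_peaks <- function(peaks, genome) {
  bad_chrom <- setdiff(unique(peaks$chrom), genome$chrom)
  if (length(bad_chrom))
    stopf("peaks on chromosomes absent from the genome: %s",
          paste(bad_chrom, collapse = ", "))
  lim <- genome$length_bp[match(peaks$chrom, genome$chrom)]
  oob <- which(peaks$end > lim)
  if (length(oob))
    stopf("%d peak(s) extend beyond chromosome ends (first: %s:%g-%g)",
          length(oob), peaks$chrom[oob[1]], peaks$start[oob[1]], peaks$end[oob[1]])
  invisible(peaks)
}

#' Read a BED file as a peak set
#'
#' Uses the standard BED reader; columns beyond chrom/start/end are ignored
#' (scores, if present, are kept).
#'
#' @param path BED3+ file path.
#' @param name optional factor name attached to the result.
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("BED file not found: '%s'", path)
  gr <- rtracklayer::import(path, format = "BED")
  score <- if (!is.null(gr$score) && !all(is.na(gr$score))) gr$score else NULL
  # GRanges is 1-based closed; convert back to 0-based half-open
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
           name = name, score = score)
}

#' Write a peak set as 3-column BED
#' @param peaks a [peak_set()].
#' @param path output path (tab-separated, no header), written atomically.
#' @export
write_peaks <- function(peaks, path) {
  write_atomic(path, function(tmp) {
    df <- data.frame(peaks$chrom,
                     format(peaks$start, scientific = FALSE, trim = TRUE),
                     format(peaks$end, scientific = FALSE, trim = TRUE))
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
}

#' Annotation model: gene bodies with exon structure
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (0-based half-open gene bodies), or NULL for an empty model.
#' @param exons data.frame with columns `gene`, `chrom`, `start`, `end`;
#'   exons must lie within their gene body. Introns are the inter-exon gaps.
#'
#' @return an `annotation_model` list with elements `genes` and `exons`;
#'   `tss(x)` gives strand-aware transcription start sites.
#' @export
annotation_model <- function(genes, exons) {
  empty_genes <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), name = character(0),
                            strand = character(0), stringsAsFactors = FALSE)
  empty_exons <- data.frame(gene = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            stringsAsFactors = FALSE)
  if (is.null(genes) || nrow(genes) == 0L)
    return(structure(list(genes = empty_genes, exons = empty_exons),
                     class = "annotation_model"))
  stopifnot(all(c("chrom", "start", "end", "name", "strand") %in% names(genes)),
            all(c("gene", "chrom", "start", "end") %in% names(exons)))
  if (!all(genes$strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  gi <- match(exons$gene, genes$name)
  if (anyNA(gi)) stopf("exon rows reference unknown genes")
  if (any(exons$start < genes$start[gi]) || any(exons$end > genes$end[gi]))
    stopf("exons must lie within their gene body")
  o <- order(genes$chrom, genes$start)
  genes <- genes[o, , drop = FALSE]; rownames(genes) <- NULL
  eo <- order(exons$gene, exons$start)
  exons <- exons[eo, , drop = FALSE]; rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "annotation_model")
}

#' Strand-aware transcription start sites of an annotation
#' @param annotation an [annotation_model()].
#' @return data.frame with `chrom`, `tss` (0-based position), `strand`,
#'   `gene`.
#' @export
tss <- function(annotation) {
  g <- annotation$genes
  data.frame(chrom = g$chrom,
             tss = ifelse(g$strand == "+", g$start, g$end - 1),
             strand = g$strand, gene = g$name, stringsAsFactors = FALSE)
}

#' Derive introns (inter-exon gaps) of an annotation
#' @param annotation an [annotation_model()].
#' @return data.frame with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open), zero rows for single-exon genes.
#' @export
introns <- function(annotation) {
  ex <- annotation$exons
  out <- lapply(split(ex, ex$gene), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    data.frame(gene = e$gene[1], chrom = e$chrom[1],
               start = e$end[-nrow(e)], end = e$start[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0))
  rownames(out) <- NULL
  out
}

#' Read a BED12 gene annotation
#' @param path BED12 file path (blockStarts relative, strand in column 6).
#' @return an [annotation_model()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: '%s'", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) return(annotation_model(NULL, NULL))
  if (is.null(gr$blocks)) stopf("annotation must be BED12 (block structure required)")
  genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      name = gr$name,
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  bl <- gr$blocks   # IRangesList, 1-based relative to gene start
  nb <- S4Vectors::elementNROWS(bl)
  ubl <- BiocGenerics::unlist(bl, use.names = FALSE)
  exons <- data.frame(gene = rep(genes$name, nb),
                      chrom = rep(genes$chrom, nb),
                      start = rep(genes$start, nb) + IRanges::start(ubl) - 1L,
                      end = rep(genes$start, nb) + IRanges::end(ubl),
                      stringsAsFactors = FALSE)
  annotation_model(genes, exons)
}

#' Write an annotation as BED12
#' @param annotation an [annotation_model()].
#' @param path output path, written atomically.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  write_atomic(path, function(tmp) {
    if (nrow(g) == 0L) { file.create(tmp); return(invisible()) }
    rows <- vapply(seq_len(nrow(g)), function(i) {
      e <- annotation$exons[annotation$exons$gene == g$name[i], , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      sizes <- paste0(paste(format(e$end - e$start, scientific = FALSE, trim = TRUE),
                            collapse = ","), ",")
      starts <- paste0(paste(format(e$start - g$start[i], scientific = FALSE, trim = TRUE),
                             collapse = ","), ",")
      paste(g$chrom[i],
            format(g$start[i], scientific = FALSE, trim = TRUE),
            format(g$end[i], scientific = FALSE, trim = TRUE),
            g$name[i], 0L, g$strand[i],
            format(g$start[i], scientific = FALSE, trim = TRUE),
            format(g$end[i], scientific = FALSE, trim = TRUE),
            "0", nrow(e), sizes, starts, sep = "\t")
    }, character(1))
    writeLines(rows, tmp)
  })
}
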