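## Peak-level summaries against a gene annotation: genomic-feature
## classification of peak midpoints and the TSS composite (metagene) profile.

## is each position covered by any interval of the (chrom, start, end) table?
point_in_intervals <- function(chrom, pos, ivl) {
  hit <- logical(length(pos))
  if (nrow(ivl) == 0L || length(pos) == 0L) return(hit)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    sub <- ivl[ivl$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) next
    m <- merge_intervals(sub$start, sub$end)
    i <- findInterval(pos[qi], m$start)
    hit[qi] <- i > 0L & pos[qi] < m$end[pmax(i, 1L)]
  }
  hit
}

#' Classify peaks by genomic feature
#'
#' Each peak is assigned exactly one category by the position of its
#' midpoint, with precedence upstream > exon > intron > others. "Upstream"
#' is the strand-aware window of `upstream_bp` bases ending at the TSS
#' (before the gene start on +, after the gene end on -).
#'
#' @param peaks a [peak_set()].
#' @param annotation an [annotation_model()].
#' @param upstream_bp length of the upstream window, bp (default 2000).
#'
#' @return a `peak_classification` list: `peaks` (data.frame with `chrom`,
#'   `start`, `end`, `midpoint`, `category`) and `summary` (data.frame with
#'   `category`, `n`, `fraction`; fractions sum to 1).
#' @export
classify_peaks <- function(peaks, annotation, upstream_bp = 2000) {
  stopifnot(inherits(peaks, "peak_set"), inherits(annotation, "annotation_model"))
  mid <- floor((peaks$start + peaks$end) / 2)
  g <- annotation$genes
  up <- if (nrow(g)) {
    data.frame(chrom = g$chrom,
               start = ifelse(g$strand == "+", pmax(0, g$start - upstream_bp), g$end),
               end = ifelse(g$strand == "+", g$start, g$end + upstream_bp),
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  up <- up[up$end > up$start, , drop = FALSE]

  cat_vec <- rep("others", nrow(peaks))
  in_intron <- point_in_intervals(peaks$chrom, mid, introns(annotation))
  cat_vec[in_intron] <- "intron"
  in_exon <- point_in_intervals(peaks$chrom, mid, annotation$exons)
  cat_vec[in_exon] <- "exon"
  in_up <- point_in_intervals(peaks$chrom, mid, up)
  cat_vec[in_up] <- "upstream"

  levels <- c("upstream", "exon", "intron", "others")
  n <- vapply(levels, function(l) sum(cat_vec == l), integer(1))
  summary <- data.frame(category = levels, n = n,
                        fraction = if (nrow(peaks)) n / nrow(peaks) else rep(NA_real_, 4),
                        stringsAsFactors = FALSE)
  structure(list(peaks = data.frame(chrom = peaks$chrom, start = peaks$start,
                                    end = peaks$end, midpoint = mid,
                                    category = cat_vec, stringsAsFactors = FALSE),
                 summary = summary, upstream_bp = upstream_bp),
            class = "peak_classification")
}

#' @export
print.peak_classification <- function(x, ...) {
  cat(sprintf("Peak classification (upstream window %d bp):\n", x$upstream_bp))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Composite (metagene) profile of peak midpoints around TSSs
#'
#' For every transcription start site, offsets of peak midpoints within
#' `flank` bp are collected (sign-flipped for minus-strand genes, so
#' positive offsets are always downstream of transcription), binned, and
#' normalized to counts per 1000 TSSs per bin.
#'
#' @param peaks a [peak_set()].
#' @param annotation an [annotation_model()].
#' @param flank half-width of the window around each TSS, bp (default 5000);
#'   must be a multiple of `bin`.
#' @param bin bin width, bp (default 100).
#'
#' @return a `composite_profile` data.frame with `bin_start`, `bin_end`
#'   (offsets relative to the TSS, bins tiling [-flank, +flank)), `count`
#'   (pairs of peak midpoint and TSS in the bin) and `density` (count per
#'   1000 TSSs); attributes `n_tss`, `flank`, `bin`.
#' @export
tss_composite <- function(peaks, annotation, flank = 5000, bin = 100) {
  stopifnot(inherits(peaks, "peak_set"), inherits(annotation, "annotation_model"))
  if (flank %% bin != 0) stopf("flank must be a multiple of bin")
  sites <- tss(annotation)
  nbin <- 2L * flank / bin
  edges <- seq(-flank, flank, by = bin)
  counts <- integer(nbin)
  if (nrow(sites) && nrow(peaks)) {
    mid <- floor((peaks$start + peaks$end) / 2)
    for (ch in unique(sites$chrom)) {
      mids <- sort(mid[peaks$chrom == ch])
      if (!length(mids)) next
      sub <- sites[sites$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        lo <- findInterval(sub$tss[i] - flank - 1, mids) + 1L
        hi <- findInterval(sub$tss[i] + flank, mids)
        if (hi < lo) next
        off <- mids[lo:hi] - sub$tss[i]
        if (sub$strand[i] == "-") off <- -off
        idx <- floor((off + flank) / bin) + 1L
        idx <- idx[idx >= 1L & idx <= nbin]
        counts <- counts + tabulate(idx, nbin)
      }
    }
  }
  prof <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                     count = counts,
                     density = if (nrow(sites)) counts / nrow(sites) * 1000 else NA_real_)
  attr(prof, "n_tss") <- nrow(sites)
  attr(prof, "flank") <- flank
  attr(prof, "bin") <- bin
  class(prof) <- c("composite_profile", "data.frame")
  prof
}
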