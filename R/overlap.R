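## Co-bound peak counting (Venn-style overlap of two peak sets).
##
## A peak of factor A is "co-bound" when its overlap with the union of
## factor B's peaks totals at least `min_overlap_bp` bases. The count is
## computed with a sorted sweep over merged intervals: B's intervals are
## merged into disjoint runs per chromosome, their cumulative covered length
## is indexed by a prefix sum, and each A peak's covered overlap is read off
## with two binary searches — O((n + m) log m) rather than the O(n * m)
## all-pairs scan, which serves as the test oracle.

## merge sorted intervals (0-based half-open) into disjoint runs
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- numeric(length(start)); me <- numeric(length(start))
  k <- 1L; ms[1] <- start[1]; me[1] <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me[k]) {
      if (end[i] > me[k]) me[k] <- end[i]
    } else {
      k <- k + 1L; ms[k] <- start[i]; me[k] <- end[i]
    }
  }
  list(start = ms[seq_len(k)], end = me[seq_len(k)])
}

## total covered overlap of each query interval with a merged interval set
covered_overlap <- function(q_start, q_end, m_start, m_end) {
  if (length(m_start) == 0L) return(numeric(length(q_start)))
  # cumulative covered length up to position p (p any coordinate):
  # cum(p) = prefix[i] + max(0, p - m_start[i+1]) clipped, via findInterval
  lens <- m_end - m_start
  prefix <- c(0, cumsum(lens))
  cum_at <- function(p) {
    i <- findInterval(p, m_start)          # last merged run starting <= p
    inside <- pmin(pmax(p - m_start[pmax(i, 1L)], 0), lens[pmax(i, 1L)])
    inside[i == 0L] <- 0
    prefix[pmax(i, 1L)] * (i > 0L) + inside * (i > 0L)
  }
  cum_at(q_end) - cum_at(q_start)
}

#' Co-bound peaks between two peak sets
#'
#' @param peaks_a,peaks_b [peak_set()] objects.
#' @param min_overlap_bp minimum total overlap (bp) of a peak with the other
#'   set's merged intervals for it to count as co-bound (default 1).
#'
#' @return an `overlap_result` list: `n_a`, `n_b`, `cobound_a` (peaks of A
#'   overlapped by >= 1 peak of B, each counted once), `cobound_b`,
#'   `unique_a`, `unique_b`, `cobound_regions` (disjoint genomic regions
#'   covered by both sets), `min_overlap_bp`, and per-factor names. The
#'   definition is not symmetric: `cobound_a` need not equal `cobound_b`.
#' @export
#'
#' @examples
#' a <- peak_set("chr1", 0, 300)
#' b <- peak_set(c("chr1", "chr1"), c(10, 100), c(20, 110))
#' cobound(a, b)
cobound <- function(peaks_a, peaks_b, min_overlap_bp = 1) {
  stopifnot(inherits(peaks_a, "peak_set"), inherits(peaks_b, "peak_set"))
  if (min_overlap_bp < 1) stopf("min_overlap_bp must be >= 1")

  count_covered <- function(q, s) {
    if (nrow(q) == 0L) return(0L)
    hits <- 0L
    for (ch in unique(q$chrom)) {
      qi <- q[q$chrom == ch, , drop = FALSE]
      si <- s[s$chrom == ch, , drop = FALSE]
      m <- merge_intervals(si$start, si$end)
      ov <- covered_overlap(qi$start, qi$end, m$start, m$end)
      hits <- hits + sum(ov >= min_overlap_bp)
    }
    hits
  }
  ca <- count_covered(peaks_a, peaks_b)
  cb <- count_covered(peaks_b, peaks_a)

  # disjoint regions covered by both sets: intersect the two merged covers
  regions <- 0L
  for (ch in union(unique(peaks_a$chrom), unique(peaks_b$chrom))) {
    ma <- merge_intervals(peaks_a$start[peaks_a$chrom == ch],
                          peaks_a$end[peaks_a$chrom == ch])
    mb <- merge_intervals(peaks_b$start[peaks_b$chrom == ch],
                          peaks_b$end[peaks_b$chrom == ch])
    if (!length(ma$start) || !length(mb$start)) next
    i <- 1L; j <- 1L
    while (i <= length(ma$start) && j <= length(mb$start)) {
      lo <- max(ma$start[i], mb$start[j])
      hi <- min(ma$end[i], mb$end[j])
      if (hi - lo >= min_overlap_bp) regions <- regions + 1L
      if (ma$end[i] < mb$end[j]) i <- i + 1L else j <- j + 1L
    }
  }

  res <- list(n_a = nrow(peaks_a), n_b = nrow(peaks_b),
              cobound_a = ca, cobound_b = cb,
              unique_a = nrow(peaks_a) - ca, unique_b = nrow(peaks_b) - cb,
              cobound_regions = regions,
              min_overlap_bp = min_overlap_bp,
              name_a = attr(peaks_a, "factor_name") %||% "A",
              name_b = attr(peaks_b, "factor_name") %||% "B")
  class(res) <- "overlap_result"
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Peak overlap (min %d bp):\n", x$min_overlap_bp))
  cat(sprintf("  %s: %d peaks, %d co-bound, %d unique\n",
              x$name_a, x$n_a, x$cobound_a, x$unique_a))
  cat(sprintf("  %s: %d peaks, %d co-bound, %d unique\n",
              x$name_b, x$n_b, x$cobound_b, x$unique_b))
  cat(sprintf("  co-bound regions (merged): %d\n", x$cobound_regions))
  invisible(x)
}

#' @export
as.data.frame.overlap_result <- function(x, ...) {
  data.frame(metric = c("n_a", "n_b", "cobound_a", "cobound_b",
                        "unique_a", "unique_b", "cobound_regions",
                        "min_overlap_bp"),
             value = c(x$n_a, x$n_b, x$cobound_a, x$cobound_b,
                       x$unique_a, x$unique_b, x$cobound_regions,
                       x$min_overlap_bp))
}
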