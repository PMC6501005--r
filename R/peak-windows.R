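## Megabase-window observed/expected enrichment of peak sets.
##
## Two-step procedure: (1) count peaks per fixed-width window tiling every
## chromosome; (2) per window, divide the observed count by the chromosome's
## expected count — total peaks on the chromosome divided by the number of
## windows on that chromosome — and flag windows whose ratio exceeds a fold
## threshold (default 1.5). The per-chromosome expectation makes the mean
## ratio on each chromosome exactly 1, so enrichment is always relative to
## the chromosome's own peak density.

#' Tile a genome into fixed-width windows
#'
#' @param genome a [genome_model()].
#' @param width window width in bp (default 1 Mb). The last window on each
#'   chromosome may be shorter.
#'
#' @return a `window_grid` data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and attributes `genome`, `width`.
#' @export
#'
#' @examples
#' tile_windows(genome_model("chr1", 2.5e6), width = 1e6)
tile_windows <- function(genome, width = 1e6) {
  if (!inherits(genome, "genome_model")) genome <- genome_model(genome$chrom, genome$length_bp)
  if (width <= 0) stopf("width must be > 0")
  per <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length_bp[i]
    n <- ceiling(L / width)
    start <- (seq_len(n) - 1) * width
    data.frame(chrom = genome$chrom[i], start = start,
               end = pmin(start + width, L), stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, per)
  rownames(grid) <- NULL
  attr(grid, "genome") <- genome
  attr(grid, "width") <- width
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' Count peaks per window
#'
#' With the default midpoint assignment each peak lands in exactly one
#' window — the one containing `floor((start + end) / 2)` — so window counts
#' sum to the number of peaks. `assignment = "overlap"` instead counts a
#' peak in every window it intersects (not count-conserving; provided for
#' sensitivity analysis).
#'
#' @param peaks a [peak_set()].
#' @param grid a [tile_windows()] grid.
#' @param assignment `"midpoint"` (default) or `"overlap"`.
#'
#' @return a `window_track` data.frame: `chrom`, `start`, `end`, `count`,
#'   with attributes `width`, `assignment`, `factor_name`.
#' @export
count_peaks_in_windows <- function(peaks, grid, assignment = c("midpoint", "overlap")) {
  assignment <- match.arg(assignment)
  stopifnot(inherits(grid, "window_grid"))
  genome <- attr(grid, "genome")
  width <- attr(grid, "width")
  validate_peaks(peaks, genome)

  counts <- integer(nrow(grid))
  # windows of one chromosome are contiguous rows; index arithmetic per chrom
  first_row <- match(genome$chrom, grid$chrom)
  if (nrow(peaks)) {
    ci <- match(peaks$chrom, genome$chrom)
    if (assignment == "midpoint") {
      mid <- floor((peaks$start + peaks$end) / 2)
      idx <- first_row[ci] + floor(mid / width)
      tab <- tabulate(idx, nbins = nrow(grid))
      counts <- counts + tab
    } else {
      w_lo <- floor(peaks$start / width)
      w_hi <- floor((peaks$end - 1) / width)   # last base covered
      for (k in seq_len(nrow(peaks))) {
        idx <- first_row[ci[k]] + (w_lo[k]:w_hi[k])
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  track <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                      count = counts, stringsAsFactors = FALSE)
  attr(track, "width") <- width
  attr(track, "assignment") <- assignment
  attr(track, "factor_name") <- attr(peaks, "factor_name")
  class(track) <- c("window_track", "data.frame")
  track
}

#' Observed/expected enrichment ratios per window
#'
#' The expected count of a window is its chromosome's total peak count
#' divided by the number of windows on that chromosome (the short terminal
#' window counts as one window). The ratio is observed/expected; windows are
#' flagged when the ratio is strictly above `fold`. Chromosomes with zero
#' total peaks get `NA` ratios and `FALSE` flags.
#'
#' @param track a counts-only [count_peaks_in_windows()] track.
#' @param fold fold threshold for the enrichment flag (default 1.5; strict
#'   `>` comparison).
#'
#' @return the track with added columns `expected`, `ratio`, `flag`.
#' @export
#'
#' @examples
#' g <- genome_model("chr1", 2.5e6)
#' tr <- count_peaks_in_windows(peak_set("chr1", c(1, 2, 3), c(10, 20, 30)),
#'                              tile_windows(g))
#' enrichment_ratio(tr)
enrichment_ratio <- function(track, fold = 1.5) {
  stopifnot(inherits(track, "window_track"), "count" %in% names(track))
  tot <- tapply(track$count, track$chrom, sum)
  nwin <- tapply(track$count, track$chrom, length)
  expected <- as.numeric(tot[track$chrom] / nwin[track$chrom])
  ratio <- ifelse(expected > 0, track$count / expected, NA_real_)
  track$expected <- expected
  track$ratio <- ratio
  track$flag <- !is.na(ratio) & ratio > fold
  attr(track, "fold") <- fold
  track
}

#' Permutation correlation of two window tracks
#'
#' Computes the rank (Spearman, default) or Pearson correlation of the two
#' tracks' enrichment ratios over windows where both are defined, and a
#' permutation p-value: one track's window values are randomly permuted
#' `n_permutations` times and
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_permutations)`.
#'
#' @param track_a,track_b [enrichment_ratio()] tracks on the same window
#'   grid (a counts-only track works too with `on = "count"`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_permutations number of random permutations (default 10000).
#' @param seed integer seed for the permutation null.
#' @param on which column to correlate: `"ratio"` (default) or `"count"`.
#' @param per_chromosome also report r per chromosome (no permutation test).
#'
#' @return a `correlation_result` list: `method`, `on`, `r`, `n_windows`,
#'   `n_permutations`, `p_value`, `seed`, and optionally `per_chromosome`.
#' @export
window_correlation <- function(track_a, track_b, method = c("spearman", "pearson"),
                               n_permutations = 10000L, seed = NULL,
                               on = c("ratio", "count"),
                               per_chromosome = FALSE) {
  method <- match.arg(method)
  on <- match.arg(on)
  stopifnot(inherits(track_a, "window_track"), inherits(track_b, "window_track"))
  if (nrow(track_a) != nrow(track_b) ||
      !all(track_a$chrom == track_b$chrom & track_a$start == track_b$start))
    stopf("tracks must share the same window grid")
  x <- track_a[[on]]; y <- track_b[[on]]
  if (is.null(x) || is.null(y))
    stopf("tracks lack the '%s' column; run enrichment_ratio() first", on)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10L) stopf("need >= 10 windows defined in both tracks")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) stopf("degenerate track (zero variance)")

  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r_obs <- cor(x, y)

  n_permutations <- as.integer(n_permutations)
  perm <- with_seed(seed, {
    Y <- vapply(seq_len(n_permutations), function(i) sample(y), numeric(length(y)))
    as.numeric(cor(x, Y))
  })
  p <- (1 + sum(abs(perm) >= abs(r_obs))) / (1 + n_permutations)

  res <- list(method = method, on = on, r = r_obs, n_windows = sum(ok),
              n_permutations = n_permutations, p_value = p, seed = seed)
  if (per_chromosome) {
    chr <- track_a$chrom[ok]
    res$per_chromosome <- vapply(split(seq_along(x), chr), function(i) {
      if (length(i) < 3L || sd(x[i]) == 0 || sd(y[i]) == 0) return(NA_real_)
      cor(x[i], y[i])
    }, numeric(1))
  }
  class(res) <- "correlation_result"
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Window correlation (%s on %s): r = %.4f over %d windows\n",
              x$method, x$on, x$r, x$n_windows))
  cat(sprintf("Permutation p = %.4g (%d permutations, seed %s)\n",
              x$p_value, x$n_permutations,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

#' Write a window track as TSV and bedGraph
#'
#' @param track an [enrichment_ratio()] track.
#' @param prefix output path prefix; writes `<prefix>.tsv` (all columns) and
#'   `<prefix>.bedGraph` (chrom, start, end, ratio; NA ratios written as 0).
#' @return invisibly, the paths written.
#' @export
write_window_track <- function(track, prefix) {
  tsv <- paste0(prefix, ".tsv")
  bg <- paste0(prefix, ".bedGraph")
  write_tsv_atomic(as.data.frame(track), tsv)
  write_atomic(bg, function(tmp) {
    ratio <- if ("ratio" %in% names(track)) ifelse(is.na(track$ratio), 0, track$ratio)
             else track$count
    df <- data.frame(track$chrom,
                     format(track$start, scientific = FALSE, trim = TRUE),
                     format(track$end, scientific = FALSE, trim = TRUE),
                     format(ratio, trim = TRUE))
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
  invisible(c(tsv, bg))
}
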