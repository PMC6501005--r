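## Synthetic ChIP-seq peak sets with planted window-level enrichment.
##
## The generator works window by window on a megabase tiling of the genome:
## the peak count of factor A in window w is Poisson(lambda * m_A(w)) where
## m_A is 1 in background windows and `multiplier` in a planted fraction of
## enriched windows. Factor B shares a fraction `coupling` of A's enriched
## windows (m_B = m_A there); its remaining enriched windows are drawn
## independently from the background windows. Peak start positions are
## uniform within the window and never cross the window boundary, so the
## planted per-window counts are exact (analysis code must still handle
## boundary-crossing peaks from real files).

#' Parameters for synthetic peak-set generation
#'
#' @param window_width window width in bp (default 1 Mb).
#' @param base_rate expected peaks per background window (Poisson lambda,
#'   must be > 0).
#' @param multiplier dimensionless enrichment multiplier (>= 0) applied to
#'   the rate in enriched windows.
#' @param enriched_fraction fraction of windows planted as enriched in each
#'   factor, in [0, 1].
#' @param coupling rho in [0, 1]: fraction of factor A's enriched windows
#'   that factor B shares.
#' @param peak_length peak length in bp: a single value, or `c(lo, hi)` for
#'   uniform lengths.
#' @param seed integer seed; identical seeds give identical peak sets.
#'
#' @return a validated `peak_sim_params` list.
#' @export
peak_sim_params <- function(window_width = 1e6, base_rate = 10,
                            multiplier = 1, enriched_fraction = 0,
                            coupling = 0, peak_length = 500, seed = NULL) {
  p <- list(window_width = as.numeric(window_width),
            base_rate = as.numeric(base_rate),
            multiplier = as.numeric(multiplier),
            enriched_fraction = as.numeric(enriched_fraction),
            coupling = as.numeric(coupling),
            peak_length = as.numeric(peak_length), seed = seed)
  if (p$window_width <= 0) stopf("window_width must be > 0")
  if (p$base_rate <= 0) stopf("base_rate (lambda) must be > 0")
  if (p$multiplier < 0) stopf("multiplier must be >= 0")
  if (p$enriched_fraction < 0 || p$enriched_fraction > 1)
    stopf("enriched_fraction must lie in [0, 1]")
  if (p$coupling < 0 || p$coupling > 1) stopf("coupling must lie in [0, 1]")
  if (any(p$peak_length < 1) || length(p$peak_length) > 2)
    stopf("peak_length must be a positive length or c(lo, hi) range")
  class(p) <- "peak_sim_params"
  p
}

#' Generate two coupled synthetic peak sets
#'
#' @param genome a [genome_model()].
#' @param params a [peak_sim_params()].
#'
#' @return list with `peaks_a`, `peaks_b` (each a [peak_set()]), and `truth`
#'   (data.frame, one row per window: planted multipliers and enrichment
#'   flags per factor; `coupling` stored as an attribute).
#' @export
#'
#' @examples
#' g <- genome_model("chr1", 20e6)
#' sim <- make_peak_sets(g, peak_sim_params(base_rate = 5, seed = 1))
#' nrow(sim$peaks_a)
make_peak_sets <- function(genome, params) {
  stopifnot(inherits(params, "peak_sim_params"))
  if (!inherits(genome, "genome_model")) genome <- genome_model(genome$chrom, genome$length_bp)
  if (params$window_width > max(genome$length_bp))
    stopf("window_width (%g bp) exceeds the longest chromosome (%g bp)",
          params$window_width, max(genome$length_bp))

  grid <- tile_windows(genome, width = params$window_width)
  nw <- nrow(grid)

  with_seed(params$seed, {
    n_enr <- round(params$enriched_fraction * nw)
    enr_a <- sort(sample.int(nw, n_enr))
    n_shared <- round(params$coupling * n_enr)
    shared <- if (n_shared > 0) sort(sample(enr_a, n_shared)) else integer(0)
    pool <- setdiff(seq_len(nw), enr_a)
    n_own <- n_enr - n_shared
    own <- if (n_own > 0) sort(sample(pool, n_own)) else integer(0)
    enr_b <- sort(c(shared, own))

    mult_a <- rep(1, nw); mult_a[enr_a] <- params$multiplier
    mult_b <- rep(1, nw); mult_b[enr_b] <- params$multiplier

    gen_factor <- function(mult) {
      counts <- rpois(nw, params$base_rate * mult)
      tot <- sum(counts)
      widx <- rep.int(seq_len(nw), counts)
      len <- if (length(params$peak_length) == 2L)
        round(runif(tot, params$peak_length[1], params$peak_length[2]))
      else rep(params$peak_length, tot)
      ws <- grid$start[widx]; we <- grid$end[widx]
      # start uniform in [ws, max(ws, we - len)]; end truncated at window end
      # (= chromosome end for terminal windows)
      hi <- pmax(ws, we - len)
      start <- floor(runif(tot, ws, hi + 1))
      start <- pmin(start, hi)
      end <- pmin(start + len, we)
      ps <- peak_set(grid$chrom[widx], start, end)
      list(peaks = ps, counts = counts)
    }
    a <- gen_factor(mult_a)
    b <- gen_factor(mult_b)

    truth <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                        mult_a = mult_a, mult_b = mult_b,
                        enriched_a = seq_len(nw) %in% enr_a,
                        enriched_b = seq_len(nw) %in% enr_b,
                        count_a = a$counts, count_b = b$counts)
    attr(truth, "coupling") <- params$coupling
    list(peaks_a = a$peaks, peaks_b = b$peaks, truth = truth)
  })
}

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping gene models on the genome, each with a
#' strand, 1 to `max_exons` exons (first exon starts at the gene start, last
#' ends at the gene end), and introns derivable as inter-exon gaps.
#'
#' @param genome a [genome_model()].
#' @param n_genes number of genes (>= 0).
#' @param seed integer seed.
#' @param gene_length `c(lo, hi)` gene length range in bp.
#' @param max_exons maximum exon count per gene.
#' @param max_tries placement attempts per gene.
#'
#' @return an [annotation_model()] (empty when `n_genes = 0`).
#' @export
make_annotation <- function(genome, n_genes, seed = NULL,
                            gene_length = c(5e3, 5e4), max_exons = 5L,
                            max_tries = 200L) {
  if (n_genes < 0) stopf("n_genes must be >= 0")
  if (n_genes == 0) return(annotation_model(genes = NULL, exons = NULL))
  with_seed(seed, {
    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    for (i in seq_len(n_genes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ci <- sample.int(nrow(genome), 1)
        L <- genome$length_bp[ci]
        glen <- round(runif(1, gene_length[1], min(gene_length[2], L)))
        if (glen < 200 || glen > L) next
        gstart <- floor(runif(1, 0, L - glen + 1))
        gend <- gstart + glen
        same <- placed[placed$chrom == genome$chrom[ci], , drop = FALSE]
        if (nrow(same) && any(same$start < gend & gstart < same$end)) next
        strand <- sample(c("+", "-"), 1)
        k <- sample.int(max_exons, 1)
        # split the gene into k exons and k-1 introns: draw 2k-1 segment
        # weights, exons at odd positions; enforce >= 50 bp per segment
        nseg <- 2L * k - 1L
        if (glen < nseg * 50) k <- 1L
        if (k == 1L) {
          ex <- data.frame(start = gstart, end = gend)
        } else {
          wts <- runif(2L * k - 1L, 0.5, 1.5)
          lens <- pmax(50, floor(wts / sum(wts) * glen))
          lens[length(lens)] <- glen - sum(lens[-length(lens)])
          if (lens[length(lens)] < 50) next
          bounds <- gstart + cumsum(c(0, lens))
          odd <- seq(1, nseg, by = 2)
          ex <- data.frame(start = bounds[odd], end = bounds[odd + 1])
        }
        gid <- sprintf("gene%04d", i)
        genes[[i]] <- data.frame(chrom = genome$chrom[ci], start = gstart,
                                 end = gend, name = gid, strand = strand,
                                 stringsAsFactors = FALSE)
        exons[[i]] <- data.frame(gene = gid, chrom = genome$chrom[ci],
                                 start = ex$start, end = ex$end,
                                 stringsAsFactors = FALSE)
        placed <- rbind(placed, genes[[i]][, c("chrom", "start", "end")])
        ok <- TRUE
        break
      }
      if (!ok) stopf("could not place %d non-overlapping genes (failed at gene %d)", n_genes, i)
    }
    annotation_model(do.call(rbind, genes), do.call(rbind, exons))
  })
}
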