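# Independent oracles and small fixture builders used across the suite.

# Brute-force per-pixel radial binning profile: bins every masked pixel by
# its true normalized elliptical radius (from the planted truth) and averages
# intensity per bin. Independent of the ray-sampling code path.
oracle_radial_binning <- function(sim, nbin = 100) {
  tr <- sim$truth
  rn <- periscope:::elliptical_radius(
    nrow(sim$intensity), ncol(sim$intensity),
    c(tr$center_row, tr$center_col), c(tr$semi_a, tr$semi_b), tr$rotation)
  b <- pmin(floor(rn[sim$mask] * nbin) + 1L, nbin)
  v <- tapply(sim$intensity[sim$mask], b, mean)
  list(f = (as.numeric(names(v)) - 0.5) / nbin, v = as.numeric(v))
}

# relative RMS between a radial profile and the binning oracle over a
# radius-fraction range
oracle_rms <- function(profile, oracle, lo = 0.05, hi = 0.95) {
  sel <- profile$radius_fractions >= lo & profile$radius_fractions <= hi
  ov <- stats::approx(oracle$f, oracle$v,
                      xout = profile$radius_fractions[sel], rule = 2)$y
  sqrt(mean((profile$mean_intensity[sel] - ov)^2)) / mean(ov)
}

# O(n*m) all-pairs co-bound count: peaks of `a` whose total overlap with the
# merged cover of `b` reaches min_overlap_bp. Independent of the sweep code.
brute_force_cobound <- function(a, b, min_overlap_bp = 1) {
  hits <- 0L
  for (i in seq_len(nrow(a))) {
    cover <- 0
    sel <- which(b$chrom == a$chrom[i])
    if (length(sel)) {
      # merge b intervals overlapping this peak, then sum covered length
      s <- pmax(b$start[sel], a$start[i]); e <- pmin(b$end[sel], a$end[i])
      keep <- which(e > s)
      if (length(keep)) {
        o <- order(s[keep]); s <- s[keep][o]; e <- e[keep][o]
        cur_s <- s[1]; cur_e <- e[1]
        for (k in seq_along(s)[-1]) {
          if (s[k] <= cur_e) cur_e <- max(cur_e, e[k])
          else { cover <- cover + (cur_e - cur_s); cur_s <- s[k]; cur_e <- e[k] }
        }
        cover <- cover + (cur_e - cur_s)
      }
    }
    if (cover >= min_overlap_bp) hits <- hits + 1L
  }
  hits
}

# random peak fixture on a small genome
random_peak_fixture <- function(n, genome, max_len = 5000, seed = NULL) {
  withr::with_seed(seed, {
    ci <- sample.int(nrow(genome), n, replace = TRUE)
    len <- sample.int(max_len, n, replace = TRUE)
    start <- floor(runif(n, 0, genome$length_bp[ci] - len))
    peak_set(genome$chrom[ci], start, start + len)
  })
}

# counter-clockwise 90-degree rotation of a matrix
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# axis-aligned disk image: constant intensity inside, 0 outside
disk_image <- function(size, center, radius, value = 100) {
  rows <- matrix(seq_len(size[1]), size[1], size[2])
  cols <- matrix(rep(seq_len(size[2]), each = size[1]), size[1], size[2])
  mask <- (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
  img <- matrix(0, size[1], size[2])
  img[mask] <- value
  list(intensity = img, mask = mask)
}
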