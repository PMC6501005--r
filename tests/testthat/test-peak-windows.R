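toy <- genome_model("chr1", 2.5e6)

test_that("window tiling covers each chromosome with ceil(L/width) windows", {
  grid <- tile_windows(toy, width = 1e6)
  expect_equal(grid$start, c(0, 1e6, 2e6))
  expect_equal(grid$end, c(1e6, 2e6, 2.5e6))

  one <- tile_windows(genome_model("chrA", 1e6))
  expect_equal(nrow(one), 1L)

  hg19chr1 <- tile_windows(genome_model("chr1", 249250621))
  expect_equal(nrow(hg19chr1), 250L)

  expect_error(tile_windows(genome_model(character(0), numeric(0))),
               "at least one")
  expect_error(tile_windows(toy, width = 0), "width")
})

test_that("midpoint assignment puts each peak in exactly one window", {
  grid <- tile_windows(toy)
  peaks <- peak_set(c("chr1", "chr1"), c(50, 1450000), c(150, 1550000))
  tr <- count_peaks_in_windows(peaks, grid)
  expect_equal(tr$count, c(1L, 1L, 0L))

  # midpoint exactly on a window boundary goes to the later window
  # (half-open convention): [999950, 1000050) has midpoint 1000000
  edge <- peak_set("chr1", 999950, 1000050)
  expect_equal(count_peaks_in_windows(edge, grid)$count, c(0L, 1L, 0L))

  empty <- peak_set(character(0), numeric(0), numeric(0))
  expect_equal(count_peaks_in_windows(empty, grid)$count, c(0L, 0L, 0L))

  stray <- peak_set("chrX", 10, 20)
  expect_error(count_peaks_in_windows(stray, grid), "chrX")
})

test_that("overlap assignment counts boundary-crossing peaks in every window", {
  grid <- tile_windows(toy)
  peaks <- peak_set("chr1", 999950, 1000050)
  tr <- count_peaks_in_windows(peaks, grid, assignment = "overlap")
  expect_equal(tr$count, c(1L, 1L, 0L))
  # midpoint mode conserves the total, overlap mode need not
  expect_equal(sum(count_peaks_in_windows(peaks, grid)$count), 1L)
  expect_equal(sum(tr$count), 2L)
})

test_that("window counts are conserved on random fixtures", {
  g <- genome_model(c("chr1", "chr2", "chr3"), c(7.3e6, 4.1e6, 2.9e6))
  grid <- tile_windows(g)
  for (s in 1:20) {
    peaks <- random_peak_fixture(sample.int(300, 1), g, seed = 1000 + s)
    tr <- count_peaks_in_windows(peaks, grid)
    expect_identical(sum(tr$count), nrow(peaks))
  }
})

test_that("enrichment ratios normalize per chromosome", {
  grid <- tile_windows(toy)
  tr <- count_peaks_in_windows(peak_set(rep("chr1", 9),
                                        c(rep(1e5, 6), rep(1.1e6, 3)),
                                        c(rep(1e5, 6), rep(1.1e6, 3)) + 100),
                               grid)
  expect_equal(tr$count, c(6L, 3L, 0L))
  er <- enrichment_ratio(tr)
  expect_equal(er$expected, rep(3, 3))
  expect_equal(er$ratio, c(2, 1, 0))
  expect_equal(er$flag, c(TRUE, FALSE, FALSE))

  # all equal counts: ratios exactly 1, no flags
  g4 <- genome_model("chr1", 4e6)
  tr4 <- count_peaks_in_windows(
    peak_set(rep("chr1", 4), (0:3) * 1e6 + 100, (0:3) * 1e6 + 200),
    tile_windows(g4))
  er4 <- enrichment_ratio(tr4)
  expect_equal(er4$ratio, rep(1, 4))
  expect_false(any(er4$flag))

  # per-chromosome, not global, expectation
  g2 <- genome_model(c("chrA", "chrB"), c(2e6, 2e6))
  tr2 <- count_peaks_in_windows(
    peak_set(c(rep("chrA", 4), rep("chrB", 4)),
             c(rep(1e5, 4), rep(1.1e6, 4)),
             c(rep(1e5, 4), rep(1.1e6, 4)) + 50),
    tile_windows(g2))
  er2 <- enrichment_ratio(tr2)
  expect_equal(er2$ratio, c(2, 0, 0, 2))
  expect_equal(er2$expected, rep(2, 4))
})

test_that("zero-peak chromosomes get undefined ratios and false flags", {
  g2 <- genome_model(c("chrA", "chrB"), c(2e6, 2e6))
  tr <- count_peaks_in_windows(peak_set("chrA", c(1e5, 1.2e6), c(2e5, 1.3e6)),
                               tile_windows(g2))
  er <- enrichment_ratio(tr)
  expect_true(all(is.na(er$ratio[er$chrom == "chrB"])))
  expect_false(any(er$flag[er$chrom == "chrB"]))
  expect_equal(er$ratio[er$chrom == "chrA"], c(1, 1))
})

test_that("per-chromosome mean ratio is exactly 1 on random fixtures", {
  g <- genome_model(c("chr1", "chr2"), c(9.7e6, 5.2e6))
  grid <- tile_windows(g)
  for (s in 1:20) {
    peaks <- random_peak_fixture(250, g, seed = 2000 + s)
    er <- enrichment_ratio(count_peaks_in_windows(peaks, grid))
    means <- tapply(er$ratio, er$chrom, mean)
    expect_true(all(abs(means - 1) < 1e-9))
  }
})

test_that("identical tracks give r = 1 and the minimal permutation p", {
  g <- genome_model("chr1", 50e6)
  sim <- make_peak_sets(g, peak_sim_params(base_rate = 10, seed = 12))
  grid <- tile_windows(g)
  tr <- enrichment_ratio(count_peaks_in_windows(sim$peaks_a, grid))
  res <- window_correlation(tr, tr, n_permutations = 500, seed = 3)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 501)
  expect_equal(res$n_windows, 50L)
})

test_that("permutation p-value and r are seeded and bounded", {
  g <- genome_model("chr1", 40e6)
  sim <- make_peak_sets(g, peak_sim_params(base_rate = 10, seed = 13))
  sim2 <- make_peak_sets(g, peak_sim_params(base_rate = 10, seed = 14))
  grid <- tile_windows(g)
  ta <- enrichment_ratio(count_peaks_in_windows(sim$peaks_a, grid))
  tb <- enrichment_ratio(count_peaks_in_windows(sim2$peaks_a, grid))
  r1 <- window_correlation(ta, tb, n_permutations = 300, seed = 5)
  r2 <- window_correlation(ta, tb, n_permutations = 300, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$r, -1); expect_lte(r1$r, 1)
  expect_gt(r1$p_value, 0); expect_lte(r1$p_value, 1)
  # pearson option and per-chromosome report
  rp <- window_correlation(ta, tb, method = "pearson", n_permutations = 100,
                           seed = 6, per_chromosome = TRUE)
  expect_equal(rp$method, "pearson")
  expect_named(rp$per_chromosome, "chr1")
})

test_that("degenerate and mismatched tracks are rejected", {
  g <- genome_model("chr1", 20e6)
  grid <- tile_windows(g)
  flat <- enrichment_ratio(count_peaks_in_windows(
    peak_set(rep("chr1", 20), (0:19) * 1e6 + 10, (0:19) * 1e6 + 20), grid))
  varying <- enrichment_ratio(count_peaks_in_windows(
    random_peak_fixture(100, g, seed = 1), grid))
  expect_error(window_correlation(flat, varying, n_permutations = 10),
               "degenerate")
  short_grid <- tile_windows(genome_model("chr1", 5e6))
  short <- enrichment_ratio(count_peaks_in_windows(
    random_peak_fixture(30, genome_model("chr1", 5e6), seed = 2), short_grid))
  expect_error(window_correlation(short, short, n_permutations = 10),
               ">= 10 windows")
  expect_error(window_correlation(varying, short, n_permutations = 10),
               "same window grid")
})

test_that("planted coupling is detected as significant co-enrichment", {
  g <- genome_model("chr1", 500e6)
  sim <- make_peak_sets(g, peak_sim_params(base_rate = 10, multiplier = 8,
                                           enriched_fraction = 0.2,
                                           coupling = 0.8, seed = 31))
  grid <- tile_windows(g)
  ta <- enrichment_ratio(count_peaks_in_windows(sim$peaks_a, grid))
  tb <- enrichment_ratio(count_peaks_in_windows(sim$peaks_b, grid))
  res <- window_correlation(ta, tb, n_permutations = 2000, seed = 32)
  expect_gt(res$r, 0.3)
  expect_lte(res$p_value, 0.001)
  # Pearson responds more strongly to the co-enriched outlying windows
  resp <- window_correlation(ta, tb, method = "pearson",
                             n_permutations = 2000, seed = 32)
  expect_gt(resp$r, 0.5)
  expect_lte(resp$p_value, 0.001)
})
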