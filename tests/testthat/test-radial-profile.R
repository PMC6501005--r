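test_that("segmentation finds disjoint bright nuclei and applies filters", {
  img <- matrix(0, 120, 120)
  d1 <- disk_image(c(120, 120), c(35, 35), 15)
  d2 <- disk_image(c(120, 120), c(85, 85), 15)
  img[d1$mask] <- 100; img[d2$mask] <- 150
  img[60, 60] <- 120  # 1-px speck

  recs <- segment_nuclei(img, min_area = 50)
  expect_length(recs, 2L)
  expect_true(all(vapply(recs, function(r) r$area, numeric(1)) > 600))

  # speck survives only with a permissive min_area
  expect_length(segment_nuclei(img, min_area = 1), 3L)

  # disk intersecting the border is dropped under the default policy
  img2 <- img
  d3 <- disk_image(c(120, 120), c(5, 60), 12)
  img2[d3$mask] <- 100
  expect_length(segment_nuclei(img2, min_area = 50), 2L)
  expect_length(segment_nuclei(img2, min_area = 50, border_policy = "keep"), 3L)

  expect_error(segment_nuclei(array(0, c(4, 4, 2))), "2-D")
})

test_that("segmentation accepts labeled and binary mask images", {
  co <- make_nucleus_cohort(5, image_size = c(256, 256), seed = 2)
  recs <- segment_nuclei(co$intensity, mask = co$labels, min_area = 50)
  expect_length(recs, 5L)
  # binary mask is re-labeled by connectivity
  recs2 <- segment_nuclei(co$intensity, mask = (co$labels > 0) * 255L,
                          min_area = 50)
  expect_length(recs2, 5L)
})

test_that("centroid sits inside the mask and respects the weighting option", {
  d <- disk_image(c(64, 64), c(30, 34), 12)
  rec <- nucleus_record(d$intensity, d$mask)
  expect_equal(rec$centroid, c(30, 34), tolerance = 1e-6)
  # intensity weighting pulls the centroid toward a bright spot
  img <- d$intensity
  img[30, 40] <- 5000
  recw <- nucleus_record(img, d$mask, centroid = "intensity")
  expect_gt(recw$centroid[2], rec$centroid[2])
})

test_that("flat-field nuclei give constant profiles", {
  # any mask shape: circle, ellipse, rotated ellipse
  shapes <- list(
    nucleus_sim_params(semi_axes = c(35, 35)),
    nucleus_sim_params(semi_axes = c(45, 25)),
    nucleus_sim_params(semi_axes = c(45, 25), rotation = 0.6))
  for (p in shapes) {
    sim <- make_nucleus_image(p)
    prof <- radial_scan(nucleus_record(sim$intensity, sim$mask))
    dev <- abs(prof$mean_intensity - 100) / 100
    expect_lt(max(dev[1:(prof$n_points - 2)]), 0.02)
  }
})

test_that("planted ring appears at the right radius with the right contrast", {
  sim <- make_nucleus_image(nucleus_sim_params(ring_start = 0.75,
                                               ring_contrast = 4,
                                               base_intensity = 100))
  prof <- radial_scan(nucleus_record(sim$intensity, sim$mask))
  f <- prof$radius_fractions
  expect_lt(max(abs(prof$mean_intensity[f < 0.7] - 100)), 2)
  expect_lt(max(abs(prof$mean_intensity[f > 0.8] - 400)), 8)
  # transition near 0.75: profile crosses 250 inside [0.70, 0.80]
  cross <- f[which(prof$mean_intensity > 250)[1]]
  expect_gt(cross, 0.70)
  expect_lt(cross, 0.80)
})

test_that("profiles are invariant under 90-degree rotation and translation", {
  sim <- make_nucleus_image(nucleus_sim_params(semi_axes = c(40, 26),
                                               rotation = 0.4,
                                               ring_start = 0.75,
                                               ring_contrast = 4))
  ref <- radial_scan(nucleus_record(sim$intensity, sim$mask))
  scale <- mean(ref$mean_intensity)

  rimg <- rot90(sim$intensity); rmask <- rot90(sim$mask)
  prot <- radial_scan(nucleus_record(rimg, rmask))
  expect_lt(sqrt(mean((prot$mean_intensity - ref$mean_intensity)^2)) / scale,
            0.01)

  # integer-pixel translation by embedding in a larger canvas
  big <- matrix(0, 160, 160); bigm <- matrix(FALSE, 160, 160)
  big[17:144, 23:150] <- sim$intensity
  bigm[17:144, 23:150] <- sim$mask
  ptr <- radial_scan(nucleus_record(big, bigm))
  expect_lt(sqrt(mean((ptr$mean_intensity - ref$mean_intensity)^2)) / scale,
            0.01)
})

test_that("ray sampling matches the per-pixel radial binning oracle", {
  # nuclei large enough that pixel-level smearing of the planted step does
  # not dominate the comparison
  fixtures <- list(
    nucleus_sim_params(image_size = c(256, 256), semi_axes = c(90, 70),
                       ring_start = 0.75, ring_contrast = 4),
    nucleus_sim_params(image_size = c(256, 256), semi_axes = c(90, 70),
                       rotation = 0.8, ring_start = 0.6, ring_contrast = 2),
    nucleus_sim_params(image_size = c(256, 256), semi_axes = c(85, 85)))
  for (p in fixtures) {
    sim <- make_nucleus_image(p)
    prof <- radial_scan(nucleus_record(sim$intensity, sim$mask))
    expect_lt(oracle_rms(prof, oracle_radial_binning(sim)), 0.05)
  }
})

test_that("mean profile equals the arithmetic mean of per-line samples", {
  sim <- make_nucleus_image(nucleus_sim_params(ring_contrast = 3,
                                               noise_sd = 20, seed = 4))
  prof <- radial_scan(nucleus_record(sim$intensity, sim$mask))
  expect_identical(prof$mean_intensity, colMeans(prof$per_line_intensity))
  expect_equal(dim(prof$per_line_intensity), c(200L, 200L))
  expect_equal(range(prof$radius_fractions), c(0, 1))
})

test_that("degenerate nuclei are rejected", {
  m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE; m[5, 6] <- TRUE
  expect_error(radial_scan(nucleus_record(matrix(1, 10, 10), m)),
               "degenerate nucleus")
  # centroid outside the mask (crescent built from two disks)
  d1 <- disk_image(c(80, 80), c(40, 40), 25)
  d2 <- disk_image(c(80, 80), c(40, 30), 20)
  cres <- d1$mask & !d2$mask
  rec <- structure(list(label = 1L, intensity = matrix(100, 80, 80) * cres,
                        mask = cres, centroid = c(40, 40), offset = c(0, 0),
                        area = sum(cres)), class = "nucleus_record")
  expect_error(radial_scan(rec), "degenerate nucleus")
})

test_that("profile aggregation gives pointwise mean and population SD", {
  mkprof <- function(val) {
    sim <- disk_image(c(90, 90), c(45, 45), 30, value = val)
    radial_scan(nucleus_record(sim$intensity, sim$mask), n_points = 50)
  }
  p10 <- mkprof(10); p20 <- mkprof(20)
  agg <- aggregate_profiles(list(p10, p20))
  expect_equal(agg$n_nuclei, 2L)
  expect_equal(agg$mean_intensity, rep(15, 50))
  expect_equal(agg$sd_intensity, rep(5, 50))

  single <- aggregate_profiles(list(p10))
  expect_equal(single$mean_intensity, p10$mean_intensity)
  expect_equal(single$sd_intensity, rep(0, 50))

  expect_error(aggregate_profiles(list()), "at least one")
  p_short <- radial_scan(nucleus_record(disk_image(c(90, 90), c(45, 45), 30)$intensity,
                                        disk_image(c(90, 90), c(45, 45), 30)$mask),
                         n_points = 40)
  expect_error(aggregate_profiles(list(p10, p_short)), "mixed n_points")
})

test_that("MFI summary behaves on constant, step and ring profiles", {
  const_prof <- structure(list(radius_fractions = seq(0, 1, length.out = 200),
                               mean_intensity = rep(7, 200)),
                          class = "radial_profile")
  s <- mfi_summary(const_prof)
  expect_equal(s$center_mfi, 7)
  expect_equal(s$periphery_mfi, 7)
  expect_equal(s$peripheral_enrichment, 1)

  f <- seq(0, 1, length.out = 200)
  step_prof <- structure(list(radius_fractions = f,
                              mean_intensity = as.numeric(f >= 0.75)),
                         class = "radial_profile")
  s2 <- mfi_summary(step_prof)
  expect_equal(s2$center_mfi, 0)
  expect_equal(s2$periphery_mfi, 1)
  expect_true(s2$undefined)
  expect_true(is.na(s2$peripheral_enrichment))

  sim <- make_nucleus_image(nucleus_sim_params(ring_start = 0.75,
                                               ring_contrast = 4))
  s3 <- mfi_summary(radial_scan(nucleus_record(sim$intensity, sim$mask)))
  expect_lt(abs(s3$peripheral_enrichment - 4) / 4, 0.15)

  expect_error(mfi_summary(const_prof, center_frac = 0.8,
                           periphery_frac = 0.75), "center_frac")
})

test_that("condition comparison orders conditions by planted contrast", {
  make_cohort_agg <- function(contrast, seed) {
    co <- make_nucleus_cohort(6, image_size = c(320, 320),
                              param_ranges = list(ring_contrast = rep(contrast, 2),
                                                  noise_sd = c(10, 10)),
                              seed = seed)
    recs <- segment_nuclei(co$intensity, mask = co$labels, min_area = 100)
    aggregate_profiles(lapply(recs, radial_scan, n_lines = 100, n_points = 100))
  }
  a1 <- make_cohort_agg(1, 21)
  a4 <- make_cohort_agg(4, 22)
  cmp <- compare_conditions(list(flat = a1, ring = a4))
  expect_setequal(unique(cmp$profiles$condition), c("flat", "ring"))
  expect_equal(nrow(cmp$mfi), 2L)
  e <- setNames(cmp$mfi$peripheral_enrichment, cmp$mfi$condition)
  expect_gt(e["ring"], e["flat"])

  expect_error(compare_conditions(list(only = a1)), ">= 2")
  expect_error(compare_conditions(setNames(list(a1, a4), c("x", "x"))),
               "unique")
  # identical cohorts give identical rows
  cmp2 <- compare_conditions(list(u = a1, v = a1))
  expect_equal(cmp2$profiles$mean[cmp2$profiles$condition == "u"],
               cmp2$profiles$mean[cmp2$profiles$condition == "v"])
})
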