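## Radial (center-to-periphery) fluorescence profiling of segmented nuclei.
##
## For each nucleus, 200 rays are cast from the centroid at uniformly spaced
## angles; each ray ends at the last mask pixel along its direction (so the
## nuclear boundary, as defined by the mask, is normalized radius 1 on every
## ray, even for mildly non-convex nuclei). Each ray is sampled at 200
## points, at radius fractions j/(n_points-1) including both the centroid
## and the boundary, by mask-renormalized bilinear interpolation of the
## intensity image (boundary samples never average in background). The
## per-nucleus profile is the pointwise mean over rays; cohorts are
## aggregated pointwise (mean and population SD across nuclei); the
## center-vs-periphery MFI summary averages the profile over inner and outer
## radius bands.

#' Segment nuclei from a grayscale image
#'
#' Thresholds the image (Otsu by default), labels connected components, and
#' returns one record per surviving nucleus. A pre-computed mask image can
#' be supplied instead (nonzero = nucleus; distinct integer labels are kept,
#' a binary mask is re-labeled by connectivity).
#'
#' @param image 2-D numeric matrix of non-negative intensities (AFU).
#' @param mask optional matrix of the same size: 0 = background, nonzero =
#'   nucleus label.
#' @param min_area minimum component area in pixels (default 200).
#' @param threshold_method `"otsu"` (default) or a numeric threshold in AFU.
#' @param border_policy `"exclude"` (default) drops components touching the
#'   image border; `"keep"` keeps them.
#' @param centroid `"binary"` (default, unweighted mask centroid) or
#'   `"intensity"` (intensity-weighted).
#'
#' @return list of `nucleus_record`s, each with `label`, `intensity` and
#'   `mask` patches (mask padded so it never touches the patch border),
#'   `centroid` (row, col; sub-pixel, patch coordinates), `offset` (row, col
#'   of patch origin in the full image) and `area`. Empty list when nothing
#'   survives.
#' @export
segment_nuclei <- function(image, mask = NULL, min_area = 200,
                           threshold_method = "otsu",
                           border_policy = c("exclude", "keep"),
                           centroid = c("binary", "intensity")) {
  border_policy <- match.arg(border_policy)
  centroid <- match.arg(centroid)
  if (!is.matrix(image) || !is.numeric(image)) stopf("image must be a 2-D numeric matrix")
  if (any(image < 0)) stopf("image intensities must be non-negative")

  if (is.null(mask)) {
    thr <- if (identical(threshold_method, "otsu")) {
      rng <- range(image)
      if (rng[2] <= rng[1]) stopf("constant image cannot be thresholded")
      norm <- (image - rng[1]) / (rng[2] - rng[1])
      rng[1] + EBImage::otsu(EBImage::Image(norm)) * (rng[2] - rng[1])
    } else if (is.numeric(threshold_method)) threshold_method
    else stopf("threshold_method must be 'otsu' or a numeric threshold")
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(image > thr)))
  } else {
    if (!all(dim(mask) == dim(image))) stopf("mask must match image dimensions")
    labs <- sort(unique(mask[mask != 0]))
    if (length(labs) <= 1L) {
      labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask != 0)))
    } else labels <- mask
  }
  labels <- matrix(as.integer(labels), nrow(image), ncol(image))

  records <- list()
  for (lab in setdiff(sort(unique(as.vector(labels))), 0L)) {
    px <- which(labels == lab, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    touches <- any(px[, 1] %in% c(1L, nrow(image))) || any(px[, 2] %in% c(1L, ncol(image)))
    if (touches && border_policy == "exclude") next
    r0 <- max(1L, min(px[, 1]) - 2L); r1 <- min(nrow(image), max(px[, 1]) + 2L)
    c0 <- max(1L, min(px[, 2]) - 2L); c1 <- min(ncol(image), max(px[, 2]) + 2L)
    m <- labels[r0:r1, c0:c1] == lab
    patch <- image[r0:r1, c0:c1]
    patch[!m] <- 0
    cen <- if (centroid == "intensity" && sum(patch[m]) > 0) {
      w <- patch[m]
      idx <- which(m, arr.ind = TRUE)
      c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
    } else {
      idx <- which(m, arr.ind = TRUE)
      colMeans(idx)
    }
    rec <- list(label = lab, intensity = patch, mask = m,
                centroid = unname(cen), offset = c(r0, c0) - 1L,
                area = sum(m))
    class(rec) <- "nucleus_record"
    records[[length(records) + 1L]] <- rec
  }
  records
}

#' Construct a nucleus record directly from an intensity patch and mask
#'
#' @param intensity 2-D numeric matrix (AFU).
#' @param mask logical matrix of the same size, one connected region.
#' @param label integer id.
#' @param centroid `"binary"` or `"intensity"` centroid.
#' @return a `nucleus_record`.
#' @export
nucleus_record <- function(intensity, mask, label = 1L,
                           centroid = c("binary", "intensity")) {
  centroid <- match.arg(centroid)
  stopifnot(is.matrix(intensity), is.logical(mask),
            all(dim(intensity) == dim(mask)))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("degenerate nucleus")
  cen <- if (centroid == "intensity" && sum(intensity[mask]) > 0)
    c(sum(idx[, 1] * intensity[mask]), sum(idx[, 2] * intensity[mask])) / sum(intensity[mask])
  else colMeans(idx)
  structure(list(label = as.integer(label), intensity = intensity, mask = mask,
                 centroid = unname(cen), offset = c(0L, 0L), area = nrow(idx)),
            class = "nucleus_record")
}

## Bilinear interpolation of matrix img at fractional (row, col) positions.
## When a mask is supplied, corner weights are renormalized over masked
## pixels, so boundary samples never average in background: a sample whose
## 2x2 cell contains >= 1 masked pixel takes the masked-weighted value; a
## sample with no masked neighbor (outside the nucleus, e.g. across a
## concavity) falls back to the plain interpolated image value.
bilinear <- function(img, r, c, mask = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  idx <- cbind(i00, i00 + 1, i00 + nr, i00 + nr + 1)
  w <- cbind((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc)
  v <- matrix(img[idx], nrow(idx), 4L)
  plain <- rowSums(w * v)
  if (is.null(mask)) return(plain)
  m <- matrix(mask[idx], nrow(idx), 4L)
  wm <- w * m
  tot <- rowSums(wm)
  ifelse(tot > 0, rowSums(wm * v) / ifelse(tot > 0, tot, 1), plain)
}

#' Radial line-scan profile of one nucleus
#'
#' Casts `n_lines` rays from the centroid at angles 2*pi*k/n_lines
#' (k = 0..n_lines-1, angle 0 along the +column axis, counter-clockwise),
#' truncates each ray at the last mask pixel along its direction, samples
#' `n_points` positions per ray at radius fractions j/(n_points-1), and
#' averages over rays.
#'
#' @param nucleus a `nucleus_record`.
#' @param n_lines number of rays (default 200).
#' @param n_points samples per ray (default 200).
#' @param keep_lines keep the full n_lines x n_points sample matrix.
#' @param step ray-march step in pixels used to locate the boundary
#'   (default 0.25).
#'
#' @return a `radial_profile` list: `label`, `n_lines`, `n_points`,
#'   `radius_fractions` (length n_points, spanning [0, 1]),
#'   `mean_intensity` (AFU per point, mean over rays), `ray_length_px`
#'   (per-ray boundary distance), and `per_line_intensity` (matrix, rays in
#'   rows) when `keep_lines = TRUE`.
#' @export
radial_scan <- function(nucleus, n_lines = 200L, n_points = 200L,
                        keep_lines = TRUE, step = 0.25) {
  stopifnot(inherits(nucleus, "nucleus_record"))
  if (n_lines < 1L || n_points < 2L) stopf("need n_lines >= 1 and n_points >= 2")
  mask <- nucleus$mask
  if (sum(mask) < 4L) stopf("degenerate nucleus")
  cen <- nucleus$centroid
  ci <- round(cen)
  if (ci[1] < 1 || ci[1] > nrow(mask) || ci[2] < 1 || ci[2] > ncol(mask) ||
      !mask[ci[1], ci[2]])
    stopf("degenerate nucleus")

  theta <- 2 * pi * (seq_len(n_lines) - 1L) / n_lines
  dc <- cos(theta)          # +column axis
  dr <- -sin(theta)         # row axis points down; CCW angles
  t_max <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  t_grid <- seq(0, t_max, by = step)

  # nearest-pixel mask lookup on the full (rays x march steps) grid
  R <- outer(dr, t_grid) + cen[1]
  C <- outer(dc, t_grid) + cen[2]
  ri <- round(R); ci2 <- round(C)
  inside <- ri >= 1 & ri <= nrow(mask) & ci2 >= 1 & ci2 <= ncol(mask)
  hit <- matrix(FALSE, n_lines, length(t_grid))
  hit[inside] <- mask[cbind(ri[inside], ci2[inside])]
  # last mask pixel along each ray, then sub-pixel refinement: the boundary
  # is the 0.5-crossing of the bilinearly interpolated mask just beyond the
  # last hit, which tracks the true edge to ~0.1 px instead of the up-to-
  # half-pixel bias of the last pixel center
  last_idx <- apply(hit, 1L, function(h) { w <- which(h); if (length(w)) max(w) else 1L })
  t0 <- t_grid[last_idx]
  mnum <- mask * 1
  sub <- seq(0, 1, by = 0.125)
  V <- vapply(sub, function(dt)
    bilinear(mnum, cen[1] + (t0 + dt) * dr, cen[2] + (t0 + dt) * dc),
    numeric(n_lines))
  V <- matrix(V, n_lines, length(sub))
  ray_len <- t0 + vapply(seq_len(n_lines), function(k) {
    v <- V[k, ]
    inside <- which(v >= 0.5)
    if (!length(inside)) return(0)
    j <- max(inside)
    if (j == length(sub)) return(sub[j])
    # linear interpolation to the 0.5 level between sub[j] and sub[j+1]
    sub[j] + 0.125 * (v[j] - 0.5) / (v[j] - v[j + 1])
  }, numeric(1))

  f <- (seq_len(n_points) - 1L) / (n_points - 1L)
  Rs <- cen[1] + outer(ray_len * dr, f)
  Cs <- cen[2] + outer(ray_len * dc, f)
  per_line <- matrix(bilinear(nucleus$intensity, as.vector(Rs), as.vector(Cs),
                              mask = mask),
                     n_lines, n_points)

  prof <- list(label = nucleus$label, n_lines = as.integer(n_lines),
               n_points = as.integer(n_points), radius_fractions = f,
               mean_intensity = colMeans(per_line),
               ray_length_px = ray_len)
  if (keep_lines) prof$per_line_intensity <- per_line
  class(prof) <- "radial_profile"
  prof
}

#' Aggregate radial profiles across nuclei
#'
#' @param profiles list of [radial_scan()] profiles with identical
#'   `n_points`.
#' @return a `profile_aggregate` list: `n_nuclei`, `radius_fractions`,
#'   `mean_intensity` (pointwise mean over nuclei), `sd_intensity`
#'   (pointwise population SD).
#' @export
aggregate_profiles <- function(profiles) {
  if (length(profiles) == 0L) stopf("need at least one profile")
  stopifnot(all(vapply(profiles, inherits, logical(1), "radial_profile")))
  np <- vapply(profiles, function(p) p$n_points, integer(1))
  if (length(unique(np)) != 1L) stopf("profiles have mixed n_points")
  M <- do.call(rbind, lapply(profiles, function(p) p$mean_intensity))
  mu <- colMeans(M)
  sdev <- sqrt(colMeans(sweep(M, 2, mu)^2))   # population SD
  structure(list(n_nuclei = length(profiles),
                 radius_fractions = profiles[[1]]$radius_fractions,
                 mean_intensity = mu, sd_intensity = sdev),
            class = "profile_aggregate")
}

#' Center-vs-periphery MFI summary of a radial profile
#'
#' @param profile a [radial_scan()] profile or [aggregate_profiles()]
#'   aggregate.
#' @param center_frac the center band is radius fractions in
#'   `[0, center_frac)` (default 0.25).
#' @param periphery_frac the periphery band is `[periphery_frac, 1]`
#'   (default 0.75).
#'
#' @return an `mfi_summary` list: `center_mfi`, `periphery_mfi` (AFU),
#'   `peripheral_enrichment` (periphery/center; `NA` with `undefined = TRUE`
#'   when `center_mfi <= 0`), the band bounds and point counts.
#' @export
mfi_summary <- function(profile, center_frac = 0.25, periphery_frac = 0.75) {
  if (!(center_frac > 0 && center_frac < periphery_frac && periphery_frac <= 1))
    stopf("need 0 < center_frac < periphery_frac <= 1")
  f <- profile$radius_fractions
  y <- profile$mean_intensity
  ic <- f < center_frac
  ip <- f >= periphery_frac
  if (!any(ic) || !any(ip)) stopf("a band contains no sample points")
  center <- mean(y[ic]); periphery <- mean(y[ip])
  undefined <- center <= 0
  structure(list(center_mfi = center, periphery_mfi = periphery,
                 peripheral_enrichment = if (undefined) NA_real_ else periphery / center,
                 undefined = undefined,
                 center_frac = center_frac, periphery_frac = periphery_frac,
                 n_center_points = sum(ic), n_periphery_points = sum(ip)),
            class = "mfi_summary")
}

#' @export
print.mfi_summary <- function(x, ...) {
  cat(sprintf("MFI center [0, %.2f): %.3f | periphery [%.2f, 1]: %.3f | peripheral enrichment: %s\n",
              x$center_frac, x$center_mfi, x$periphery_frac, x$periphery_mfi,
              if (x$undefined) "undefined (center MFI <= 0)"
              else sprintf("%.3f", x$peripheral_enrichment)))
  invisible(x)
}

#' Compare radial profiles across conditions
#'
#' @param aggregates named list of [aggregate_profiles()] results, one per
#'   condition (>= 2, unique names).
#' @param center_frac,periphery_frac MFI bands, see [mfi_summary()].
#'
#' @return list with `profiles` — long-format data.frame (`condition`,
#'   `radius_fraction`, `mean`, `sd`, `n_nuclei`) for center-to-periphery
#'   curves — and `mfi` — one [mfi_summary()] row per condition.
#' @export
compare_conditions <- function(aggregates, center_frac = 0.25, periphery_frac = 0.75) {
  if (length(aggregates) < 2L) stopf("need >= 2 conditions")
  labels <- names(aggregates)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels))
    stopf("conditions must have unique non-empty labels")
  stopifnot(all(vapply(aggregates, inherits, logical(1), "profile_aggregate")))
  long <- do.call(rbind, lapply(labels, function(l) {
    a <- aggregates[[l]]
    data.frame(condition = l, radius_fraction = a$radius_fractions,
               mean = a$mean_intensity, sd = a$sd_intensity,
               n_nuclei = a$n_nuclei, stringsAsFactors = FALSE)
  }))
  mfi <- do.call(rbind, lapply(labels, function(l) {
    s <- mfi_summary(aggregates[[l]], center_frac, periphery_frac)
    data.frame(condition = l, center_mfi = s$center_mfi,
               periphery_mfi = s$periphery_mfi,
               peripheral_enrichment = s$peripheral_enrichment,
               undefined = s$undefined, n_nuclei = aggregates[[l]]$n_nuclei,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- rownames(mfi) <- NULL
  list(profiles = long, mfi = mfi)
}
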