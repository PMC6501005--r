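## Synthetic nuclei with planted radial intensity structure.
##
## Each nucleus is a (possibly rotated) filled ellipse. "Normalized radius"
## is defined in the ellipse's own frame: a point at offset (u, v) along the
## semi-axes has r_norm = sqrt((u/a)^2 + (v/b)^2), so r_norm = 0 at the
## center and 1 on the boundary. Intensity is base_intensity for
## r_norm < ring_start and base_intensity * ring_contrast for
## r_norm >= ring_start (a "peripheral ring"), plus optional additive
## Gaussian noise clipped at zero. Background is exactly zero.

#' Parameters for one synthetic nucleus
#'
#' @param image_size integer (height, width) in pixels.
#' @param center numeric (row, col) center of the ellipse, pixels (1-based
#'   pixel-center coordinates).
#' @param semi_axes numeric (a, b): semi-axis lengths in pixels, both >= 4.
#' @param rotation rotation of the `a` axis, radians, counter-clockwise from
#'   the +column direction.
#' @param base_intensity baseline fluorescence, arbitrary fluorescence units
#'   (AFU).
#' @param ring_start fraction of the normalized radius in [0, 1] at which the
#'   peripheral ring begins.
#' @param ring_contrast dimensionless multiplier (>= 0) applied to intensity
#'   at normalized radius >= `ring_start`; 1 gives a flat (uniform) nucleus.
#' @param noise_sd standard deviation of additive Gaussian noise, AFU.
#' @param seed integer seed; identical seeds give bit-identical images.
#'
#' @return a `nucleus_sim_params` list, validated.
#' @export
nucleus_sim_params <- function(image_size = c(128L, 128L),
                               center = (image_size + 1) / 2,
                               semi_axes = c(40, 30),
                               rotation = 0,
                               base_intensity = 100,
                               ring_start = 0.75,
                               ring_contrast = 1,
                               noise_sd = 0,
                               seed = NULL) {
  p <- list(image_size = as.integer(image_size), center = as.numeric(center),
            semi_axes = as.numeric(semi_axes), rotation = as.numeric(rotation),
            base_intensity = as.numeric(base_intensity),
            ring_start = as.numeric(ring_start),
            ring_contrast = as.numeric(ring_contrast),
            noise_sd = as.numeric(noise_sd), seed = seed)
  validate_nucleus_sim_params(p)
  class(p) <- "nucleus_sim_params"
  p
}

validate_nucleus_sim_params <- function(p) {
  if (length(p$image_size) != 2L || any(p$image_size < 8L))
    stopf("image_size must be (height, width), each >= 8 px")
  if (length(p$semi_axes) != 2L || any(p$semi_axes < 4))
    stopf("semi_axes must be two values >= 4 px")
  if (p$ring_start < 0 || p$ring_start > 1)
    stopf("ring_start must lie in [0, 1]")
  if (p$ring_contrast < 0) stopf("ring_contrast must be >= 0")
  if (p$base_intensity < 0) stopf("base_intensity must be >= 0")
  if (p$noise_sd < 0) stopf("noise_sd must be >= 0")
  invisible(p)
}

## normalized elliptical radius of pixel grid points for one ellipse
elliptical_radius <- function(nrow_img, ncol_img, center, semi_axes, rotation) {
  rows <- matrix(seq_len(nrow_img), nrow_img, ncol_img)
  cols <- matrix(rep(seq_len(ncol_img), each = nrow_img), nrow_img, ncol_img)
  dx <- cols - center[2]          # +column axis
  dy <- -(rows - center[1])       # +row is down; flip so angles are CCW
  u <- dx * cos(rotation) + dy * sin(rotation)
  v <- -dx * sin(rotation) + dy * cos(rotation)
  sqrt((u / semi_axes[1])^2 + (v / semi_axes[2])^2)
}

## axis-aligned half-extents of a rotated ellipse bounding box
ellipse_extent <- function(semi_axes, rotation) {
  a <- semi_axes[1]; b <- semi_axes[2]
  c(row = sqrt((a * sin(rotation))^2 + (b * cos(rotation))^2),
    col = sqrt((a * cos(rotation))^2 + (b * sin(rotation))^2))
}

#' Render one synthetic nucleus
#'
#' @param params a [nucleus_sim_params()] object.
#'
#' @return list with `intensity` (numeric matrix, AFU), `mask` (logical
#'   matrix, the filled ellipse), and `truth` (one-row data.frame of the
#'   planted parameters).
#' @export
#'
#' @examples
#' sim <- make_nucleus_image(nucleus_sim_params(ring_contrast = 4, seed = 1))
#' range(sim$intensity[sim$mask])
make_nucleus_image <- function(params) {
  validate_nucleus_sim_params(params)
  h <- params$image_size[1]; w <- params$image_size[2]
  ext <- ellipse_extent(params$semi_axes, params$rotation)
  # keep a >= 2 px free margin so the mask never touches the image border
  if (params$center[1] - ext["row"] < 3 || params$center[1] + ext["row"] > h - 2 ||
      params$center[2] - ext["col"] < 3 || params$center[2] + ext["col"] > w - 2)
    stopf("nucleus touches border")

  rn <- elliptical_radius(h, w, params$center, params$semi_axes, params$rotation)
  mask <- rn <= 1
  intensity <- matrix(0, h, w)
  intensity[mask] <- params$base_intensity *
    ifelse(rn[mask] >= params$ring_start, params$ring_contrast, 1)
  if (params$noise_sd > 0) {
    noise <- with_seed(params$seed, rnorm(sum(mask), 0, params$noise_sd))
    intensity[mask] <- pmax(0, intensity[mask] + noise)
  }
  truth <- data.frame(
    nucleus = 1L,
    center_row = params$center[1], center_col = params$center[2],
    semi_a = params$semi_axes[1], semi_b = params$semi_axes[2],
    rotation = params$rotation,
    base_intensity = params$base_intensity,
    ring_start = params$ring_start, ring_contrast = params$ring_contrast,
    noise_sd = params$noise_sd)
  list(intensity = intensity, mask = mask, truth = truth)
}

#' Generate a cohort of non-overlapping synthetic nuclei in one image
#'
#' Places `n` nuclei with parameters drawn uniformly from the given ranges,
#' rejecting placements that overlap an existing nucleus or the image border.
#'
#' @param n number of nuclei (>= 1).
#' @param image_size integer (height, width) of the shared image.
#' @param param_ranges list of ranges, each a length-2 numeric `c(lo, hi)`
#'   (a single value fixes the parameter): `semi_a`, `semi_b`, `rotation`,
#'   `base_intensity`, `ring_start`, `ring_contrast`, `noise_sd`.
#' @param seed integer seed; placement and noise are reproducible.
#' @param max_tries placement attempts per nucleus before giving up.
#'
#' @return list with `intensity` (matrix), `labels` (integer matrix, 0 =
#'   background, k = nucleus k), and `truth` (data.frame, one row per
#'   nucleus).
#' @export
make_nucleus_cohort <- function(n, image_size = c(512L, 512L),
                                param_ranges = list(), seed = NULL,
                                max_tries = 200L) {
  if (n < 1) stopf("n must be >= 1")
  defaults <- list(semi_a = c(18, 28), semi_b = c(14, 22),
                   rotation = c(0, pi), base_intensity = c(100, 100),
                   ring_start = c(0.75, 0.75), ring_contrast = c(1, 1),
                   noise_sd = c(0, 0))
  rng <- utils::modifyList(defaults, param_ranges)
  draw <- function(r) if (length(r) == 1L || r[1] == r[2]) r[1] else runif(1, r[1], r[2])

  with_seed(seed, {
    h <- image_size[1]; w <- image_size[2]
    intensity <- matrix(0, h, w)
    labels <- matrix(0L, h, w)
    truth <- vector("list", n)
    centers <- matrix(NA_real_, n, 2)
    radii <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        a <- draw(rng$semi_a); b <- draw(rng$semi_b); th <- draw(rng$rotation)
        ext <- ellipse_extent(c(a, b), th)
        rmax <- max(a, b)
        if (2 * ext["row"] + 6 > h || 2 * ext["col"] + 6 > w) next
        cr <- runif(1, ext["row"] + 3, h - ext["row"] - 2)
        cc <- runif(1, ext["col"] + 3, w - ext["col"] - 2)
        if (i > 1) {
          d <- sqrt((centers[seq_len(i - 1), 1] - cr)^2 +
                    (centers[seq_len(i - 1), 2] - cc)^2)
          if (any(d < radii[seq_len(i - 1)] + rmax + 3)) next
        }
        p <- nucleus_sim_params(
          image_size = image_size, center = c(cr, cc), semi_axes = c(a, b),
          rotation = th, base_intensity = draw(rng$base_intensity),
          ring_start = draw(rng$ring_start),
          ring_contrast = draw(rng$ring_contrast),
          noise_sd = draw(rng$noise_sd), seed = NULL)
        sim <- make_nucleus_image(p)   # noise drawn from the cohort RNG stream
        intensity[sim$mask] <- sim$intensity[sim$mask]
        labels[sim$mask] <- i
        centers[i, ] <- c(cr, cc); radii[i] <- rmax
        tr <- sim$truth; tr$nucleus <- i
        truth[[i]] <- tr
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("could not place %d non-overlapping nuclei in a %dx%d image (failed at nucleus %d after %d tries)",
              n, h, w, i, max_tries)
    }
    list(intensity = intensity, labels = labels, truth = do.call(rbind, truth))
  })
}
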