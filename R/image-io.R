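## Image IO. Intensities live in arbitrary fluorescence units (AFU); on disk
## images are 16-bit grayscale TIFF (AFU stored as integer counts in
## [0, 65535]) and masks are 8-bit PNG (0 background / 255 foreground, or
## label values 1..n for labeled masks).

#' Write an intensity matrix as 16-bit grayscale TIFF
#'
#' Values are rounded to integers and must fit in [0, 65535].
#'
#' @param intensity 2-D numeric matrix, AFU.
#' @param path output path.
#' @export
write_intensity_tiff <- function(intensity, path) {
  v <- round(intensity)
  if (any(v < 0) || any(v > 65535))
    stopf("intensities must fit a 16-bit range [0, 65535] (got [%g, %g])",
          min(v), max(v))
  write_atomic(path, function(tmp) {
    tiff::writeTIFF(v / 65535, tmp, bits.per.sample = 16L)
  })
}

#' Read a grayscale TIFF as an intensity matrix (AFU)
#' @param path TIFF path (16- or 8-bit grayscale; RGB is averaged).
#' @return numeric matrix of integer AFU in [0, 65535].
#' @export
read_intensity_tiff <- function(path) {
  if (!file.exists(path)) stopf("image not found: '%s'", path)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  round(img * 65535)
}

#' Write a mask as 8-bit PNG
#'
#' A logical mask is written as 0/255; an integer label mask keeps its
#' labels (must be < 256).
#'
#' @param mask logical or integer matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  v <- if (is.logical(mask)) ifelse(mask, 255L, 0L) else as.integer(mask)
  if (any(v < 0) || any(v > 255)) stopf("mask labels must fit 8 bits")
  m <- matrix(v / 255, nrow(mask), ncol(mask))
  write_atomic(path, function(tmp) png::writePNG(m, tmp))
}

#' Read a mask PNG
#' @param path PNG path.
#' @return integer matrix of labels (0 = background); a 0/255 binary mask
#'   reads back as 0/255.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stopf("mask not found: '%s'", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Read any supported grayscale image (TIFF or PNG) as AFU
#' @param path image path; format chosen by extension.
#' @return numeric matrix (AFU; PNG scaled to [0, 255]).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) read_intensity_tiff(path)
  else if (ext == "png") {
    if (!file.exists(path)) stopf("image not found: '%s'", path)
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    round(img * 255)
  } else stopf("unsupported image format: '%s'", ext)
}

#' Write per-nucleus radial profiles as TSV
#'
#' @param profiles list of [radial_scan()] profiles.
#' @param path output TSV (`nucleus`, `point_index`, `radius_fraction`,
#'   `mean_intensity`).
#' @export
write_profiles_tsv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(nucleus = p$label,
               point_index = seq_len(p$n_points) - 1L,
               radius_fraction = p$radius_fractions,
               mean_intensity = p$mean_intensity)
  }))
  write_tsv_atomic(df, path)
}

#' Write an aggregate profile as TSV
#'
#' SD is the population standard deviation across nuclei.
#'
#' @param aggregate an [aggregate_profiles()] result.
#' @param path output TSV (`point_index`, `radius_fraction`, `mean`,
#'   `sd_population`, `n_nuclei`).
#' @export
write_aggregate_tsv <- function(aggregate, path) {
  df <- data.frame(point_index = seq_along(aggregate$radius_fractions) - 1L,
                   radius_fraction = aggregate$radius_fractions,
                   mean = aggregate$mean_intensity,
                   sd_population = aggregate$sd_intensity,
                   n_nuclei = aggregate$n_nuclei)
  write_tsv_atomic(df, path)
}

#' Write a per-line intensity matrix as flat binary + text sidecar
#'
#' The matrix is written row-major as little-endian float64, with a sidecar
#' `<path>.hdr` text file recording `rows`, `cols`, `dtype`, `order`.
#'
#' @param profile a [radial_scan()] profile with `per_line_intensity`.
#' @param path output binary path.
#' @export
write_per_line_matrix <- function(profile, path) {
  m <- profile$per_line_intensity
  if (is.null(m)) stopf("profile has no per-line matrix (keep_lines = FALSE?)")
  write_atomic(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  })
  write_atomic(paste0(path, ".hdr"), function(tmp) {
    writeLines(c(sprintf("rows\t%d", nrow(m)), sprintf("cols\t%d", ncol(m)),
                 "dtype\tfloat64", "order\trow-major", "endian\tlittle"), tmp)
  })
  invisible(path)
}
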