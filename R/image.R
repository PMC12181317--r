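#' Hyperspectral absorbance image
#'
#' A 3-D absorbance cube indexed (row, col, wavenumber) with its pixel
#' geometry and a per-pixel outlier mask. Masked pixels (`TRUE`) are
#' treated as removed and rendered white/missing in contrast maps.
#'
#' @param cube numeric array `nrow x ncol x nwavenumber`.
#' @param wavenumbers ascending numeric vector matching `dim(cube)[3]`.
#' @param pixel_size_um physical pixel edge in micrometers. A 64 x 64
#'   focal-plane-array tile imaging a 175 x 175 um field gives
#'   `175/64` um per pixel.
#' @param outlier_mask logical matrix of the cube's spatial shape;
#'   default all `FALSE`.
#' @return object of class `spectral_image`.
#' @export
spectral_image <- function(cube, wavenumbers, pixel_size_um = 175 / 64,
                           outlier_mask = NULL) {
  cube <- unclass(cube)
  if (length(dim(cube)) != 3L) stop("cube must be a 3-D array (row, col, wavenumber)")
  wavenumbers <- as.numeric(wavenumbers)
  if (dim(cube)[3] != length(wavenumbers))
    stop("cube third dimension (", dim(cube)[3], ") does not match grid length (",
         length(wavenumbers), ")")
  if (any(diff(wavenumbers) <= 0)) stop("wavenumbers must be strictly increasing")
  if (is.null(outlier_mask))
    outlier_mask <- matrix(FALSE, dim(cube)[1], dim(cube)[2])
  outlier_mask <- as.matrix(outlier_mask)
  if (!identical(dim(outlier_mask), dim(cube)[1:2]))
    stop("outlier_mask shape must equal the cube's spatial shape")
  storage.mode(cube) <- "double"
  structure(list(cube = cube, wavenumbers = wavenumbers,
                 pixel_size_um = as.numeric(pixel_size_um),
                 outlier_mask = outlier_mask),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("spectral_image: %d x %d px (%.0f x %.0f um), %d wavenumbers, %d masked\n",
              d[1], d[2], d[1] * x$pixel_size_um, d[2] * x$pixel_size_um,
              d[3], sum(x$outlier_mask)))
  invisible(x)
}

#' Assemble focal-plane-array tiles into a mosaic image
#'
#' Places equally sized tiles row-major on a `rows x cols` layout, e.g. the
#' standard 4 x 12 mosaic of 64 x 64 tiles covering 700 x 2100 um. Pixel
#' `(r, c)` of tile `(i, j)` (1-based) lands at mosaic position
#' `(64 (i-1) + r, 64 (j-1) + c)` for 64-pixel tiles.
#'
#' @param tiles list of [spectral_image()] tiles sharing shape and grid.
#' @param layout integer pair `c(rows, cols)`; `length(tiles)` must equal
#'   `rows * cols`.
#' @return a [spectral_image()] mosaic.
#' @export
assemble_mosaic <- function(tiles, layout) {
  stopifnot(length(layout) == 2L, all(layout >= 1))
  rows <- layout[1]; cols <- layout[2]
  if (length(tiles) != rows * cols)
    stop("need ", rows * cols, " tiles for a ", rows, " x ", cols,
         " layout, got ", length(tiles))
  d0 <- dim(tiles[[1]]$cube)
  wn <- tiles[[1]]$wavenumbers
  for (t in tiles) {
    if (!identical(dim(t$cube), d0)) stop("tile shapes differ")
    if (!isTRUE(all.equal(t$wavenumbers, wn))) stop("tile grids differ")
  }
  th <- d0[1]; tw <- d0[2]
  cube <- array(NA_real_, c(th * rows, tw * cols, d0[3]))
  mask <- matrix(FALSE, th * rows, tw * cols)
  k <- 0L
  for (i in seq_len(rows)) for (j in seq_len(cols)) {   # row-major placement
    k <- k + 1L
    ri <- (i - 1L) * th + seq_len(th)
    cj <- (j - 1L) * tw + seq_len(tw)
    cube[ri, cj, ] <- tiles[[k]]$cube
    mask[ri, cj] <- tiles[[k]]$outlier_mask
  }
  spectral_image(cube, wn, tiles[[1]]$pixel_size_um, mask)
}

#' Outlier filter specification for spectroscopic images
#'
#' A pixel spectrum is declared an outlier when the sum of all its
#' absorbance values is strictly less than `sum_threshold`, or its
#' absorbance at the amide-I band (nearest grid point to
#' `amide_wavenumber`) is strictly less than `amide_threshold`. Such
#' pixels carry no tissue information and mostly mark gaps in the section.
#' `sum_threshold` is meaningful only on raw absorbance spectra and scales
#' with the number of grid points, so it is a configurable default, not a
#' constant.
#'
#' @param sum_threshold minimum per-pixel absorbance sum (default 20).
#' @param amide_wavenumber amide-I position in cm^-1 (default 1650).
#' @param amide_threshold minimum amide-I absorbance (default 0.01).
#' @export
image_filter_spec <- function(sum_threshold = 20, amide_wavenumber = 1650,
                              amide_threshold = 0.01) {
  stopifnot(sum_threshold >= 0, amide_threshold >= 0)
  structure(list(sum_threshold = sum_threshold,
                 amide_wavenumber = amide_wavenumber,
                 amide_threshold = amide_threshold),
            class = "image_filter_spec")
}

#' Flag outlier pixels of a spectroscopic image
#'
#' Sets the outlier mask according to [image_filter_spec()]; cube values
#' are left untouched. Both comparisons are strict, so a pixel whose sum is
#' exactly the threshold is kept.
#'
#' @param image a [spectral_image()].
#' @param spec an [image_filter_spec()].
#' @return the image with its `outlier_mask` replaced.
#' @export
filter_image_outliers <- function(image, spec = image_filter_spec()) {
  stopifnot(inherits(image, "spectral_image"))
  amide_idx <- nearest_index(image$wavenumbers, spec$amide_wavenumber,
                             max_dist = 3)
  sums <- apply(image$cube, c(1, 2), sum)
  amide <- image$cube[, , amide_idx]
  image$outlier_mask <- (sums < spec$sum_threshold) | (amide < spec$amide_threshold)
  image
}

#' Integrated-absorbance contrast map
#'
#' Per-pixel closed-interval sum of absorbance over `[lo, hi]`; the
#' standard contrast for tissue overview images uses 950--1800 cm^-1.
#' Masked pixels are emitted as `NA` (rendered white).
#'
#' @param image a [spectral_image()].
#' @param lo,hi integration window in cm^-1.
#' @return numeric matrix of the image's spatial shape.
#' @export
contrast_image <- function(image, lo = 950, hi = 1800) {
  idx <- window_indices(image$wavenumbers, lo, hi)
  if (!length(idx)) stop("no grid points in [", lo, ", ", hi, "]")
  m <- apply(image$cube[, , idx, drop = FALSE], c(1, 2), sum)
  m[image$outlier_mask] <- NA_real_
  m
}

#' Mean spectrum with standard-deviation band
#'
#' Per-wavenumber mean and sample standard deviation (n-1 denominator) of
#' a spectrum set or of the unmasked pixels of a spectroscopic image. To
#' compensate for section-thickness and contact-pressure variation the
#' spectra are area-normalized first by default, as is standard for tissue
#' mean-spectrum plots.
#'
#' @param x a [spectrum_set()] or [spectral_image()].
#' @param area_normalize_first area-normalize before averaging
#'   (default `TRUE`).
#' @param norm_range normalization window passed to [area_normalize()];
#'   default the full stored range.
#' @return list with `wavenumbers`, `mean`, `sd` and `n`.
#' @export
mean_spectrum <- function(x, area_normalize_first = TRUE, norm_range = NULL) {
  if (inherits(x, "spectral_image")) {
    keep <- which(!x$outlier_mask)
    if (!length(keep)) stop("no unmasked pixels")
    flat <- matrix(aperm(x$cube, c(3, 1, 2)), nrow = dim(x$cube)[3])
    x <- spectrum_set(t(flat[, keep, drop = FALSE]), x$wavenumbers)
  }
  stopifnot(inherits(x, "spectrum_set"))
  if (n_spectra(x) < 1L) stop("need at least one spectrum")
  if (area_normalize_first) {
    if (is.null(norm_range)) norm_range <- range(x$wavenumbers)
    x <- area_normalize(x, norm_range)
  }
  a <- x$absorbance
  list(wavenumbers = x$wavenumbers,
       mean = colMeans(a),
       sd = if (nrow(a) >= 2L) apply(a, 2, stats::sd) else rep(NA_real_, ncol(a)),
       n = nrow(a))
}
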