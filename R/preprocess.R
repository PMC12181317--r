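#' Preprocessing chain specification
#'
#' The fixed preprocessing order for ATR point spectra is: atmospheric
#' compensation (optional) -> restriction to 950--1800 cm^-1 -> linear
#' two-point baseline correction -> restriction to the classification
#' range 950--1480 cm^-1 -> area normalization over that range -> min-max
#' normalization. Area normalization happens during spectral
#' preprocessing; min-max normalization is applied to training and test
#' sets immediately before classification. Both orders are supported via
#' `minmax_last` for sensitivity analyses.
#'
#' @param range_full full working range in cm^-1, default `c(950, 1800)`.
#' @param range_classify classification range, default `c(950, 1480)`;
#'   must lie within `range_full`.
#' @param baseline_anchors two anchor wavenumbers for the baseline line;
#'   default the endpoints of `range_full`.
#' @param area_norm_range window whose absorbance sum is scaled to 1;
#'   default `range_classify`.
#' @param atmospheric on/off switch for water-vapor compensation
#'   (default off; requires a `water_reference`).
#' @param minmax_last if `TRUE` (default) min-max follows area
#'   normalization; if `FALSE` the order is swapped.
#' @export
preprocess_spec <- function(range_full = c(950, 1800),
                            range_classify = c(950, 1480),
                            baseline_anchors = range_full,
                            area_norm_range = range_classify,
                            atmospheric = FALSE,
                            minmax_last = TRUE) {
  stopifnot(length(range_full) == 2L, range_full[1] < range_full[2],
            range_classify[1] >= range_full[1],
            range_classify[2] <= range_full[2],
            baseline_anchors[1] >= range_full[1],
            baseline_anchors[2] <= range_full[2])
  structure(list(range_full = range_full, range_classify = range_classify,
                 baseline_anchors = baseline_anchors,
                 area_norm_range = area_norm_range,
                 atmospheric = atmospheric, minmax_last = minmax_last),
            class = "preprocess_spec")
}

#' Convert single-beam spectra to absorbance
#'
#' Ratioes sample single-beam spectra against a reference single beam
#' (e.g. the bare ATR crystal) and converts to absorbance,
#' `A = -log10(S/R)`. Non-positive sample intensities are capped at
#' `cap` absorbance units with a warning; a non-positive reference is an
#' error.
#'
#' @param sample_set [spectrum_set()] of single-beam intensities.
#' @param reference numeric vector on the same grid, strictly positive.
#' @param cap absorbance assigned where the sample intensity is <= 0.
#' @return a [spectrum_set()] of absorbance spectra.
#' @export
absorbance_from_single_beam <- function(sample_set, reference, cap = 5) {
  stopifnot(inherits(sample_set, "spectrum_set"))
  reference <- as.numeric(reference)
  if (length(reference) != length(sample_set$wavenumbers))
    stop("reference must be on the sample grid")
  if (any(reference <= 0)) stop("reference single beam must be strictly positive")
  s <- sample_set$absorbance
  bad <- s <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive sample intensities capped at A = ", cap)
    s[bad] <- NA_real_
  }
  a <- -log10(sweep(s, 2, reference, "/"))
  a[bad] <- cap
  spectrum_set(a, sample_set$wavenumbers, sample_set$meta, "raw")
}

#' Restrict spectra to a wavenumber window
#'
#' Closed-interval slice: keeps every grid point `v` with
#' `lo <= v <= hi`. Never interpolates.
#'
#' @param set a [spectrum_set()].
#' @param lo,hi window bounds in cm^-1.
#' @return restricted [spectrum_set()] (state gains `range_restricted`).
#' @export
restrict_range <- function(set, lo, hi) {
  stopifnot(lo < hi)
  idx <- window_indices(set$wavenumbers, lo, hi)
  if (!length(idx)) stop("no grid points in [", lo, ", ", hi, "]")
  out <- spectrum_set(set$absorbance[, idx, drop = FALSE],
                      set$wavenumbers[idx], set$meta, set$state)
  append_state(out, "range_restricted")
}

#' Linear two-point baseline correction
#'
#' Subtracts, from each spectrum, the straight line through its values at
#' the two anchor wavenumbers (nearest grid points); the corrected
#' absorbance at both anchors is exactly zero.
#'
#' @param set a [spectrum_set()].
#' @param anchors two distinct wavenumbers inside the stored range;
#'   default the range endpoints.
#' @return corrected [spectrum_set()] (state gains `baseline_corrected`).
#' @export
baseline_correct_two_point <- function(set, anchors = range(set$wavenumbers)) {
  stopifnot(length(anchors) == 2L)
  idx <- nearest_index(set$wavenumbers, anchors)
  if (idx[1] == idx[2]) stop("baseline anchors resolve to the same grid point")
  wn <- set$wavenumbers
  x1 <- wn[idx[1]]; x2 <- wn[idx[2]]
  a <- set$absorbance
  y1 <- a[, idx[1]]; y2 <- a[, idx[2]]
  slope <- (y2 - y1) / (x2 - x1)
  base <- outer(slope, wn - x1) + y1      # n_spectra x n_wn baseline
  corrected <- a - base
  corrected[, idx] <- 0                   # anchors are zero by construction
  out <- spectrum_set(corrected, wn, set$meta, set$state)
  append_state(out, "baseline_corrected")
}

#' Area normalization
#'
#' Divides each whole spectrum by the discrete sum of its absorbance
#' values over the stated range, so that afterwards that sum equals 1.
#' The discrete sum (not a trapezoidal integral) matches the convention
#' used for the image outlier rule and is spacing-invariant after
#' normalization. Removes section-thickness / contact-pressure scaling.
#'
#' @param set a [spectrum_set()].
#' @param norm_range window in cm^-1; default `c(950, 1480)`.
#' @return normalized [spectrum_set()] (state gains `area_normalized`).
#' @export
area_normalize <- function(set, norm_range = c(950, 1480)) {
  idx <- window_indices(set$wavenumbers, norm_range[1], norm_range[2])
  if (!length(idx)) stop("normalization range contains no grid points")
  area <- rowSums(set$absorbance[, idx, drop = FALSE])
  if (any(area <= 0))
    stop("non-positive absorbance area (empty or failed measurement) in spectrum ",
         which(area <= 0)[1])
  out <- spectrum_set(set$absorbance / area, set$wavenumbers, set$meta, set$state)
  append_state(out, "area_normalized")
}

#' Min-max normalization
#'
#' Per spectrum, maps the minimum absorbance to 0 and the maximum to 1:
#' `(A - min) / (max - min)`. Constant spectra are an error.
#'
#' @param set a [spectrum_set()].
#' @return normalized [spectrum_set()] (state gains `minmax_normalized`).
#' @export
minmax_normalize <- function(set) {
  a <- set$absorbance
  lo <- apply(a, 1, min)
  hi <- apply(a, 1, max)
  if (any(hi <= lo)) stop("constant spectrum cannot be min-max normalized (spectrum ",
                          which(hi <= lo)[1], ")")
  out <- spectrum_set((a - lo) / (hi - lo), set$wavenumbers, set$meta, set$state)
  append_state(out, "minmax_normalized")
}

#' Water-vapor (atmospheric) compensation
#'
#' Subtracts a scaled water-vapor reference spectrum from each spectrum.
#' The scale is fitted per spectrum by least squares on the first
#' differences of spectrum and reference over the fit window (default
#' 1300--1800 cm^-1, where the rotational-vibrational water lines sit) and
#' clipped to be non-negative. Fitting in the difference domain makes the
#' estimate insensitive to the broad tissue bands that overlap the narrow
#' water lines: the derivative of a symmetric narrow line is antisymmetric
#' and decorrelates from the locally near-linear slope of a broad band.
#' Vendor atmospheric-compensation algorithms are proprietary; scaled
#' reference subtraction is the transparent equivalent used here.
#'
#' @param set a [spectrum_set()].
#' @param water_reference numeric vector on the set's grid.
#' @param fit_range least-squares window in cm^-1.
#' @return compensated [spectrum_set()] (state gains
#'   `atmospheric_compensated`).
#' @export
atmospheric_compensation <- function(set, water_reference,
                                     fit_range = c(1300, 1800)) {
  w <- as.numeric(water_reference)
  if (length(w) != length(set$wavenumbers))
    stop("water reference must be on the set's grid")
  idx <- window_indices(set$wavenumbers, fit_range[1], fit_range[2])
  dw <- diff(w[idx])
  ww <- sum(dw^2)
  if (ww == 0) return(append_state(set, "atmospheric_compensated"))
  ds <- t(apply(set$absorbance[, idx, drop = FALSE], 1, diff))
  alpha <- pmax(0, as.numeric(ds %*% dw) / ww)
  out <- spectrum_set(set$absorbance - outer(alpha, w), set$wavenumbers,
                      set$meta, set$state)
  append_state(out, "atmospheric_compensated")
}

#' Apply the full preprocessing chain
#'
#' Runs the chain described in [preprocess_spec()] and records each step
#' in the set's preprocessing state. The classification-path output
#' (restricted to 950--1480 cm^-1, area- and min-max-normalized) is what
#' region selection and classification operate on.
#'
#' @param set a raw [spectrum_set()] covering `spec$range_full`.
#' @param spec a [preprocess_spec()].
#' @param water_reference required when `spec$atmospheric` is `TRUE`.
#' @return preprocessed [spectrum_set()].
#' @export
preprocess_chain <- function(set, spec = preprocess_spec(),
                             water_reference = NULL) {
  stopifnot(inherits(spec, "preprocess_spec"))
  if (spec$atmospheric) {
    if (is.null(water_reference))
      stop("atmospheric compensation requested but no water_reference given")
    set <- atmospheric_compensation(set, water_reference)
  }
  set <- restrict_range(set, spec$range_full[1], spec$range_full[2])
  set <- baseline_correct_two_point(set, spec$baseline_anchors)
  set <- restrict_range(set, spec$range_classify[1], spec$range_classify[2])
  if (spec$minmax_last) {
    set <- area_normalize(set, spec$area_norm_range)
    set <- minmax_normalize(set)
  } else {
    set <- minmax_normalize(set)
    set <- area_normalize(set, spec$area_norm_range)
  }
  set
}
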