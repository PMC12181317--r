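#' Wavenumber grids
#'
#' A wavenumber grid is a strictly increasing, uniformly spaced numeric
#' vector of wavenumbers in cm^-1. Spectra are stored internally in
#' ascending wavenumber order even though FT-IR instruments conventionally
#' emit descending files; readers normalize the order so that a window such
#' as 995--1005 cm^-1 has one unambiguous index range.
#'
#' @param lo,hi first and last wavenumber (cm^-1).
#' @param by nominal point spacing (cm^-1). The default ATR grid runs
#'   950--1800 cm^-1 at 2 cm^-1; imaging grids typically use 3 cm^-1.
#' @return numeric vector of class `wavenumber_grid`.
#' @examples
#' g <- wavenumber_grid(950, 1800, by = 2)
#' length(g)  # 426 points
#' @export
wavenumber_grid <- function(lo = 950, hi = 1800, by = 2) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi, by > 0)
  g <- seq(lo, hi, by = by)
  validate_grid(g)
  structure(g, class = c("wavenumber_grid", "numeric"), spacing = by)
}

#' Validate a wavenumber vector as a uniform ascending grid
#'
#' Checks that `wn` is strictly increasing with uniform spacing
#' (max deviation from the nominal step at most 1e-6 of the step).
#'
#' @param wn numeric vector of wavenumbers.
#' @return `wn`, invisibly; errors otherwise.
#' @export
validate_grid <- function(wn) {
  if (length(wn) < 2L) stop("grid must have at least 2 points")
  d <- diff(wn)
  if (any(d <= 0)) stop("wavenumbers must be strictly increasing with no duplicates")
  step <- stats::median(d)
  if (max(abs(d - step)) > 1e-6 * step)
    stop("wavenumber grid is not uniform")
  invisible(wn)
}

#' @rdname validate_grid
#' @export
grid_spacing <- function(wn) stats::median(diff(wn))

#' Nearest-grid-point lookup
#'
#' Wavenumber-to-index lookup uses the nearest grid point; no interpolation
#' or peak fitting is performed anywhere in the pipeline.
#'
#' @param wn grid (ascending numeric).
#' @param target wavenumber(s) to locate (cm^-1).
#' @param max_dist error if the nearest point is farther than this (cm^-1);
#'   `Inf` disables the check.
#' @return integer index (vectorized over `target`).
#' @export
nearest_index <- function(wn, target, max_dist = Inf) {
  idx <- vapply(target, function(t) which.min(abs(wn - t)), integer(1))
  if (is.finite(max_dist)) {
    off <- abs(wn[idx] - target)
    if (any(off > max_dist))
      stop(sprintf("no grid point within %g cm^-1 of %g", max_dist,
                   target[which(off > max_dist)[1]]))
  }
  idx
}

#' Indices of grid points inside a closed wavenumber window
#'
#' A window `[lo, hi]` includes every grid point `v` with `lo <= v <= hi`
#' (closed interval at both ends).
#'
#' @param wn grid (ascending numeric).
#' @param lo,hi window bounds in cm^-1.
#' @return integer vector of indices (possibly empty).
#' @export
window_indices <- function(wn, lo, hi) {
  stopifnot(lo <= hi)
  which(wn >= lo & wn <= hi)
}
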