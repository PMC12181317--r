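#' Read spectra from a wide CSV table
#'
#' The on-disk format is a wide CSV whose first column is `wavenumber_cm1`
#' and whose remaining columns each hold one spectrum, plus a metadata CSV
#' mapping column names to patients, samples, slices and class labels
#' (columns `spectrum_id`, `patient_id`, `sample_id`, `slice_id`,
#' `class_label`). Files written in descending instrument order are
#' accepted; the rows are reversed so the in-memory grid is ascending, and
#' that reversal is recorded in the attribute `reversed_on_read`.
#'
#' @param path path to the spectra CSV.
#' @param meta_path path to the metadata CSV; if `NULL`, default metadata
#'   is generated (one synthetic patient per column is NOT assumed —
#'   instead an error is raised, since patient identity matters for every
#'   downstream split).
#' @param state preprocessing state to stamp on the returned set.
#' @return a [spectrum_set()].
#' @export
read_spectra_csv <- function(path, meta_path = NULL, state = "raw") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2L) stop("spectra CSV needs a wavenumber column plus at least one spectrum")
  if (names(tab)[1] != "wavenumber_cm1")
    stop("first column must be 'wavenumber_cm1', found '", names(tab)[1], "'")
  wn <- as.numeric(tab[[1]])
  if (anyNA(wn)) stop("non-numeric wavenumber values")
  reversed <- FALSE
  if (all(diff(wn) < 0)) {           # conventional descending instrument order
    tab <- tab[rev(seq_len(nrow(tab))), , drop = FALSE]
    wn <- rev(wn)
    reversed <- TRUE
  }
  if (any(diff(wn) <= 0)) stop("wavenumbers are not monotone")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (!all(is.finite(vals))) stop("spectra CSV contains non-finite values")
  ids <- colnames(vals)

  if (is.null(meta_path)) stop("metadata CSV is required (spectrum_id -> patient/sample/class)")
  md <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "patient_id", "sample_id", "slice_id", "class_label")
  if (!all(need %in% names(md))) stop("metadata CSV must have columns: ",
                                      paste(need, collapse = ", "))
  miss <- setdiff(ids, md$spectrum_id)
  if (length(miss)) stop("no metadata for spectrum column: ", miss[1])
  md <- md[match(ids, md$spectrum_id), need]

  m <- t(vals)
  dimnames(m) <- NULL
  set <- spectrum_set(m, wn, md, state)
  attr(set, "reversed_on_read") <- reversed
  set
}

#' Write spectra to a wide CSV table (plus metadata CSV)
#'
#' Columns are emitted in a deterministic order, sorted by patient, sample
#' and slice, so repeated writes of the same set are byte-identical.
#'
#' @param set a non-empty [spectrum_set()].
#' @param path output path for the spectra CSV.
#' @param meta_path output path for the metadata CSV; default replaces the
#'   extension with `_meta.csv`.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path, meta_path = default_meta_path(path)) {
  if (n_spectra(set) == 0L) stop("refusing to write an empty spectrum set")
  ord <- order(set$meta$patient_id, set$meta$sample_id, set$meta$slice_id)
  set <- subset_spectra(set, ord)
  out <- data.frame(wavenumber_cm1 = set$wavenumbers, check.names = FALSE)
  vals <- t(set$absorbance)
  colnames(vals) <- set$meta$spectrum_id
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(set$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_meta_path <- function(path) sub("(\\.[^.]*)?$", "_meta.csv", path)

#' Read and write hyperspectral absorbance cubes
#'
#' Cubes are stored in the package's native container: an RDS file holding
#' the named components `cube` (row x col x wavenumber array),
#' `wavenumbers`, `outlier_mask` (logical row x col matrix) and the scalar
#' `pixel_size_um`. The round trip is bit-exact for double precision data.
#'
#' @param path file path (conventionally `.irc.rds`).
#' @return [read_cube()] returns a [spectral_image()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  need <- c("cube", "wavenumbers", "outlier_mask", "pixel_size_um")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("cube file is missing dataset: ", miss[1])
  spectral_image(obj$cube, obj$wavenumbers, obj$pixel_size_um, obj$outlier_mask)
}

#' @rdname read_cube
#' @param image a [spectral_image()].
#' @export
write_cube <- function(image, path) {
  stopifnot(inherits(image, "spectral_image"))
  saveRDS(list(cube = image$cube, wavenumbers = image$wavenumbers,
               outlier_mask = image$outlier_mask,
               pixel_size_um = image$pixel_size_um),
          path)
  invisible(path)
}
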