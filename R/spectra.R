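#' Sets of absorbance spectra on a shared wavenumber grid
#'
#' `spectrum_set` is the universal currency of the pipeline: a matrix of
#' absorbance values (one row per spectrum, one column per wavenumber) on a
#' single ascending grid, together with per-spectrum metadata and a record
#' of the preprocessing steps applied so far.
#'
#' @param absorbance numeric matrix, spectra in rows, wavenumbers in
#'   columns (a vector is treated as a single spectrum).
#' @param wavenumbers ascending numeric vector, length `ncol(absorbance)`.
#' @param meta data frame with one row per spectrum and columns
#'   `spectrum_id`, `patient_id`, `sample_id`, `slice_id`, `class_label`.
#'   Missing columns are filled with defaults; `patient_id` must be
#'   non-empty for every spectrum.
#' @param state character vector of preprocessing steps already applied, in
#'   order, drawn from `raw`, `atmospheric_compensated`, `range_restricted`,
#'   `baseline_corrected`, `area_normalized`, `minmax_normalized`.
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(absorbance, wavenumbers, meta = NULL, state = "raw") {
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance has ", ncol(absorbance), " columns but grid has ",
         length(wavenumbers), " points")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  if (!all(is.finite(absorbance)))
    stop("absorbance values must all be finite")
  n <- nrow(absorbance)
  meta <- complete_meta(meta, n)
  state <- check_state(state)
  structure(list(absorbance = absorbance, wavenumbers = wavenumbers,
                 meta = meta, state = state),
            class = "spectrum_set")
}

VALID_STATES <- c("raw", "atmospheric_compensated", "range_restricted",
                  "baseline_corrected", "area_normalized",
                  "minmax_normalized")

ENTITY_CLASSES <- c("normal", "HCC", "CCC", "metastasis")
VALID_CLASSES <- c(ENTITY_CLASSES, "tumor", "unknown")

check_state <- function(state) {
  state <- as.character(state)
  bad <- setdiff(state, VALID_STATES)
  if (length(bad)) stop("unknown preprocessing state: ", bad[1])
  if (anyDuplicated(state)) stop("preprocessing state list has repeats")
  state
}

complete_meta <- function(meta, n) {
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n)
    stop("metadata has ", nrow(meta), " rows for ", n, " spectra")
  if (is.null(meta$patient_id)) meta$patient_id <- rep("P1", n)
  if (is.null(meta$sample_id))  meta$sample_id  <- rep("S1", n)
  if (is.null(meta$slice_id))   meta$slice_id   <- seq_len(n)
  if (is.null(meta$class_label)) meta$class_label <- rep("unknown", n)
  if (is.null(meta$spectrum_id))
    meta$spectrum_id <- sprintf("%s_%s_%s", meta$patient_id, meta$sample_id,
                                meta$slice_id)
  meta$patient_id <- as.character(meta$patient_id)
  meta$sample_id <- as.character(meta$sample_id)
  meta$class_label <- as.character(meta$class_label)
  if (any(is.na(meta$patient_id) | meta$patient_id == ""))
    stop("every spectrum needs a non-empty patient_id")
  bad <- setdiff(unique(meta$class_label), VALID_CLASSES)
  if (length(bad)) stop("unknown class label: ", bad[1])
  rownames(meta) <- NULL
  meta[c("spectrum_id", "patient_id", "sample_id", "slice_id", "class_label")]
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d spectra x %d wavenumbers (%.0f-%.0f cm^-1)\n",
              nrow(x$absorbance), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat("  patients:", length(unique(x$meta$patient_id)),
      " classes:", paste(names(table(x$meta$class_label)), collapse = "/"), "\n")
  cat("  state:", paste(x$state, collapse = " > "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set a `spectrum_set`.
#' @export
n_spectra <- function(set) nrow(set$absorbance)

#' Subset a spectrum set by spectrum index
#' @param set a `spectrum_set`.
#' @param i integer or logical index over spectra (rows).
#' @return a `spectrum_set` with the selected spectra.
#' @export
subset_spectra <- function(set, i) {
  spectrum_set(set$absorbance[i, , drop = FALSE], set$wavenumbers,
               set$meta[i, , drop = FALSE], set$state)
}

#' Combine spectrum sets sharing a grid and state
#' @param ... `spectrum_set` objects on identical grids.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  wn <- sets[[1]]$wavenumbers
  st <- sets[[1]]$state
  for (s in sets[-1]) {
    if (!isTRUE(all.equal(s$wavenumbers, wn)))
      stop("all sets must share one wavenumber grid")
    if (!identical(s$state, st))
      stop("all sets must share one preprocessing state")
  }
  spectrum_set(do.call(rbind, lapply(sets, `[[`, "absorbance")), wn,
               do.call(rbind, lapply(sets, `[[`, "meta")), st)
}

append_state <- function(set, step) {
  if (!step %in% set$state) set$state <- c(set$state, step)
  set
}

#' Preprocessing signature of a spectrum set
#'
#' A compact string recording the preprocessing chain; classification
#' refuses to score spectra whose signature differs from the one the model
#' was trained under, which prevents silently classifying un-normalized
#' spectra.
#'
#' @param set a `spectrum_set`.
#' @return character scalar.
#' @export
norm_signature <- function(set) paste(set$state, collapse = ">")

#' Merge the tumor entities into one label
#'
#' Maps HCC, CCC and metastasis to the union label `tumor`; normal is
#' unchanged. The original entity label is retained in the metadata column
#' `entity_label` so it can be recovered.
#'
#' @param set a `spectrum_set` with labels among normal/HCC/CCC/metastasis.
#' @return relabelled `spectrum_set`.
#' @export
relabel_to_tumor_union <- function(set) {
  lab <- set$meta$class_label
  bad <- setdiff(unique(lab), ENTITY_CLASSES)
  if (length(bad)) stop("cannot form tumor union from label: ", bad[1])
  set$meta$entity_label <- lab
  set$meta$class_label <- ifelse(lab == "normal", "normal", "tumor")
  set
}

#' Display colors for the tissue classes
#'
#' Fixed mapping used in all reports and figures: normal is green, the
#' pooled tumor class black, metastases red, CCC yellow, and HCC blue.
#'
#' @return named character vector of colors.
#' @export
class_palette <- function() {
  c(normal = "green", tumor = "black", metastasis = "red",
    CCC = "yellow", HCC = "blue")
}
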