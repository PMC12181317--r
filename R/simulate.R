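#' Spectral band specification
#'
#' @param center band center in cm^-1.
#' @param fwhm full width at half maximum in cm^-1 (> 0).
#' @param amplitude peak absorbance (>= 0).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return a `band_spec` list.
#' @export
band_spec <- function(center, fwhm, amplitude, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot(fwhm > 0, amplitude >= 0)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape), class = "band_spec")
}

band_profile <- function(band, wn) {
  z <- (wn - band$center) / band$fwhm
  if (band$shape == "gaussian") {
    band$amplitude * exp(-4 * log(2) * z^2)
  } else {
    band$amplitude / (1 + 4 * z^2)
  }
}

#' Per-class generative band model
#'
#' Describes one tissue class as a sum of vibrational bands plus
#' multiplicative patient- and spectrum-level variability, an affine
#' baseline, additive white noise and optional narrow water-vapor lines.
#' The patient effect is a log-normal per-band amplitude multiplier shared
#' by all of a patient's spectra, emulating the high inter-patient
#' biovariability of resected tissue and making patient-level versus
#' spectrum-level data splitting consequential; the spectrum effect is a
#' global scale factor per spectrum (section thickness, contact pressure).
#'
#' @param class one of `normal`, `HCC`, `CCC`, `metastasis`.
#' @param bands list of [band_spec()].
#' @param patient_sigma sdlog of the per-patient, per-band log-normal
#'   amplitude multipliers.
#' @param spectrum_sigma sdlog of the per-spectrum global multiplier.
#' @param noise_sd additive white-noise standard deviation (absorbance).
#' @param baseline_offset_sd,baseline_slope_sd sd of the random baseline
#'   offset (absorbance) and slope (absorbance per cm^-1).
#' @param water_vapor_amp amplitude of the water-vapor line comb
#'   (0 disables it).
#' @return a `class_band_model` list.
#' @export
class_band_model <- function(class, bands, patient_sigma = 0.2,
                             spectrum_sigma = 0.08, noise_sd = 0.004,
                             baseline_offset_sd = 0.01,
                             baseline_slope_sd = 1e-5,
                             water_vapor_amp = 0) {
  stopifnot(class %in% ENTITY_CLASSES,
            patient_sigma >= 0, spectrum_sigma >= 0, noise_sd >= 0,
            baseline_offset_sd >= 0, baseline_slope_sd >= 0,
            water_vapor_amp >= 0)
  structure(list(class = class, bands = bands, patient_sigma = patient_sigma,
                 spectrum_sigma = spectrum_sigma, noise_sd = noise_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 water_vapor_amp = water_vapor_amp),
            class = "class_band_model")
}

# Fixed comb of narrow rotational-vibrational water lines, 1300-1800 cm^-1.
water_vapor_centers <- function() {
  c(1340, 1374, 1419, 1457, 1497, 1540, 1576, 1617, 1653, 1700, 1734, 1772)
}

#' Water-vapor reference line spectrum
#'
#' The unit-amplitude comb of narrow (4 cm^-1 fwhm) lines between 1300 and
#' 1800 cm^-1 that the simulator superimposes when `water_vapor_amp > 0`;
#' the same vector serves as the reference for
#' [atmospheric_compensation()].
#'
#' @param wn wavenumber grid.
#' @return numeric vector on `wn`.
#' @export
water_vapor_reference <- function(wn) {
  prof <- numeric(length(wn))
  for (ctr in water_vapor_centers())
    prof <- prof + band_profile(band_spec(ctr, 4, 1), wn)
  prof
}

#' Default per-class band catalogue
#'
#' Band centers follow the standard tissue assignments: amide I/II at
#' 1654/1550 cm^-1, CH deformation bands at 1400/1452 cm^-1, amide III at
#' 1240/1312 cm^-1, collagen at 1282/1340 cm^-1, glycogen at 1030/1108/
#' 1154 cm^-1 and the DNA/phospholipid phosphate band at 1080 cm^-1.
#' Relative class amplitudes encode the qualitative contrasts of liver
#' tissue: glycogen highest in normal tissue, intermediate in HCC, low and
#' similar in CCC and metastases; amide-III/collagen signals (1240, 1282,
#' 1340 cm^-1) strongest in CCC (desmoplastic stroma); CH bands nearly
#' equal everywhere. The absolute amplitudes are calibration constants of
#' the generator, not estimates of real tissue chemistry.
#'
#' @param ... arguments forwarded to every [class_band_model()]
#'   (noise and variability settings).
#' @return named list of four `class_band_model`s
#'   (normal, HCC, CCC, metastasis).
#' @export
default_band_models <- function(...) {
  # center, fwhm, amplitude per class (normal, HCC, CCC, metastasis)
  cat <- rbind(
    c(1654, 45, 1.00, 1.00, 1.00, 1.00),  # amide I
    c(1550, 38, 0.70, 0.70, 0.70, 0.70),  # amide II
    c(1452, 24, 0.26, 0.26, 0.27, 0.26),  # CH3 asym deformation
    c(1400, 22, 0.22, 0.22, 0.23, 0.22),  # CH3 sym deformation
    c(1340, 18, 0.04, 0.04, 0.09, 0.04),  # collagen
    c(1312, 14, 0.05, 0.05, 0.06, 0.05),  # amide III (weak)
    c(1282, 18, 0.04, 0.04, 0.10, 0.04),  # collagen
    c(1240, 30, 0.12, 0.12, 0.20, 0.13),  # amide III / phosphate
    c(1154, 14, 0.12, 0.08, 0.03, 0.03),  # glycogen CO-O-C
    c(1108, 12, 0.08, 0.05, 0.03, 0.03),  # glycogen
    c(1080, 20, 0.18, 0.14, 0.08, 0.08),  # DNA/phospholipid phosphate
    c(1030, 30, 0.30, 0.20, 0.08, 0.08),  # glycogen C-O
    c(1000, 18, 0.04, 0.09, 0.09, 0.09),  # unassigned / water content
    c(970,  10, 0.02, 0.02, 0.05, 0.09)   # unassigned / water content
  )
  classes <- ENTITY_CLASSES
  out <- lapply(seq_along(classes), function(k) {
    bands <- lapply(seq_len(nrow(cat)), function(i)
      band_spec(cat[i, 1], cat[i, 2], cat[i, 2 + k]))
    class_band_model(classes[k], bands, ...)
  })
  names(out) <- classes
  out
}

deterministic_band_sum <- function(model, wn, band_mult = 1) {
  band_mult <- rep_len(band_mult, length(model$bands))
  prof <- numeric(length(wn))
  for (i in seq_along(model$bands)) {
    b <- model$bands[[i]]
    if (b$center < min(wn) || b$center > max(wn))
      stop("grid does not cover band center ", b$center, " cm^-1")
    prof <- prof + band_mult[i] * band_profile(b, wn)
  }
  prof
}

#' Draw a per-patient band-amplitude effect
#'
#' One log-normal multiplier per band (sdlog `model$patient_sigma`),
#' drawn once per patient and shared across all of that patient's
#' spectra. Perturbing individual band amplitudes, rather than the
#' overall scale, emulates between-patient differences in biochemical
#' composition, which survive area normalization the way real
#' biovariability does (a global scale factor would be divided out).
#'
#' @param model a [class_band_model()].
#' @return numeric vector, one multiplier per band.
#' @export
draw_patient_effect <- function(model) {
  if (model$patient_sigma > 0)
    stats::rlnorm(length(model$bands), 0, model$patient_sigma)
  else rep(1, length(model$bands))
}

#' Simulate one absorbance spectrum
#'
#' Draws one spectrum from a class model: the deterministic band sum,
#' scaled by the patient and spectrum multipliers, plus an affine random
#' baseline, water-vapor lines, and additive white noise. No non-negativity
#' clipping is applied (noise may dip below zero, as in real baselines).
#' Consumes the current RNG stream; call `set.seed()` for reproducibility.
#'
#' @param model a [class_band_model()].
#' @param grid wavenumber grid covering 950--1800 cm^-1 (or at least every
#'   band center of the model).
#' @param patient_effect per-band amplitude multiplier shared across one
#'   patient's spectra (scalar or one value per band; see
#'   [draw_patient_effect()]).
#' @param meta optional one-row metadata data frame.
#' @return a single-spectrum [spectrum_set()] in state `raw`.
#' @export
simulate_spectrum <- function(model, grid, patient_effect = 1, meta = NULL) {
  wn <- as.numeric(grid)
  prof <- deterministic_band_sum(model, wn, patient_effect)
  spec_mult <- if (model$spectrum_sigma > 0)
    stats::rlnorm(1, 0, model$spectrum_sigma) else 1
  offset <- if (model$baseline_offset_sd > 0)
    stats::rnorm(1, 0, model$baseline_offset_sd) else 0
  slope <- if (model$baseline_slope_sd > 0)
    stats::rnorm(1, 0, model$baseline_slope_sd) else 0
  a <- prof * spec_mult + offset + slope * (wn - wn[1])
  if (model$water_vapor_amp > 0)
    a <- a + model$water_vapor_amp * water_vapor_reference(wn)
  if (model$noise_sd > 0)
    a <- a + stats::rnorm(length(wn), 0, model$noise_sd)
  if (is.null(meta))
    meta <- data.frame(patient_id = "P1", sample_id = "S1", slice_id = 1L,
                       class_label = model$class)
  spectrum_set(a, wn, meta, "raw")
}

#' Cohort design for the simulator
#'
#' Specifies, per class, how many patients to draw, how many tissue
#' samples each contributes, and how many spectra (slices/cuts, typically
#' 3--8) each sample yields. `spectra_per_sample` may be a vector, recycled
#' over a class's samples, so designs can reproduce exact spectrum counts.
#'
#' @param classes named list; each element is
#'   `list(n_patients =, samples_per_patient =, spectra_per_sample =)`.
#' @export
cohort_design <- function(classes) {
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    stopifnot(nm %in% ENTITY_CLASSES,
              cl$n_patients >= 1, cl$samples_per_patient >= 1,
              all(cl$spectra_per_sample >= 1))
  }
  structure(list(classes = classes), class = "cohort_design")
}

#' Default cohort designs
#'
#' `"binary"`: 27 normal patients with 5 spectra each (135 normal spectra)
#' and 7 patients with 7 spectra each for every tumor entity (147 tumor
#' spectra across HCC, CCC and metastasis) — the spectrum counts of the
#' binary training task. `"three_class"`: 12 patients per tumor entity
#' whose per-sample counts cycle through 3--8 cuts, so that the first six
#' patients of each class yield 38 metastasis, 39 CCC and 37 HCC spectra.
#'
#' @param task `"binary"` or `"three_class"`.
#' @return a [cohort_design()].
#' @export
default_cohort_design <- function(task = c("binary", "three_class")) {
  task <- match.arg(task)
  if (task == "binary") {
    cohort_design(list(
      normal = list(n_patients = 27, samples_per_patient = 1,
                    spectra_per_sample = 5),
      HCC = list(n_patients = 7, samples_per_patient = 1,
                 spectra_per_sample = 7),
      CCC = list(n_patients = 7, samples_per_patient = 1,
                 spectra_per_sample = 7),
      metastasis = list(n_patients = 7, samples_per_patient = 1,
                        spectra_per_sample = 7)))
  } else {
    cohort_design(list(
      metastasis = list(n_patients = 12, samples_per_patient = 1,
                        spectra_per_sample = c(7, 6, 6, 6, 6, 7,  6, 7, 5, 8, 6, 6)),
      CCC = list(n_patients = 12, samples_per_patient = 1,
                 spectra_per_sample = c(7, 7, 6, 6, 6, 7,  5, 6, 8, 6, 7, 6)),
      HCC = list(n_patients = 12, samples_per_patient = 1,
                 spectra_per_sample = c(6, 6, 6, 6, 6, 7,  7, 6, 5, 8, 6, 6))))
  }
}

#' Simulate a labelled cohort of spectra
#'
#' Draws every patient's log-normal multiplier once and shares it across
#' all that patient's spectra; patient IDs are unique across classes.
#' Spectrum counts match the design exactly, and the whole cohort is
#' reproducible from `(design, models, seed)`.
#'
#' @param design a [cohort_design()].
#' @param models named list of [class_band_model()]s covering every class
#'   in the design (default [default_band_models()]).
#' @param grid wavenumber grid (default 950--1800 cm^-1 at 2 cm^-1).
#' @param seed integer seed, set explicitly.
#' @return a [spectrum_set()] in state `raw`.
#' @export
simulate_cohort <- function(design, models = default_band_models(),
                            grid = wavenumber_grid(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  pieces <- list()
  pnum <- 0L
  for (nm in names(design$classes)) {
    cl <- design$classes[[nm]]
    model <- models[[nm]]
    if (is.null(model)) stop("no band model for class ", nm)
    # the per-sample counts cycle over all of the class's samples in order
    nsp <- rep_len(cl$spectra_per_sample,
                   cl$n_patients * cl$samples_per_patient)
    samp <- 0L
    for (p in seq_len(cl$n_patients)) {
      pnum <- pnum + 1L
      pid <- sprintf("P%03d", pnum)
      p_eff <- draw_patient_effect(model)
      for (s in seq_len(cl$samples_per_patient)) {
        samp <- samp + 1L
        sid <- sprintf("%s_S%d", pid, s)
        for (k in seq_len(nsp[samp])) {
          meta <- data.frame(patient_id = pid, sample_id = sid,
                             slice_id = k, class_label = nm)
          pieces[[length(pieces) + 1L]] <-
            simulate_spectrum(model, grid, p_eff, meta)
        }
      }
    }
  }
  do.call(bind_spectra, pieces)
}

#' Simulate a focal-plane-array spectroscopic image
#'
#' Builds a mosaic of 64 x 64 pixel tiles at 175/64 um per pixel, e.g.
#' `shape = c(4, 12)` gives 256 x 768 pixels spanning 700 x 2100 um. A
#' fraction `gap_fraction` of pixels is drawn as gaps in the tissue
#' section: near-zero absorbance (amide-I below 0.01 by construction), so
#' the outlier filter should remove approximately that fraction. The index
#' of gap pixels is attached as attribute `gap_index` for verification.
#'
#' @param model a [class_band_model()].
#' @param shape tile layout `c(rows, cols)`.
#' @param gap_fraction fraction of gap pixels in `[0, 1]`.
#' @param grid wavenumber grid (default 950--1800 cm^-1 at 3 cm^-1, the
#'   typical imaging spacing).
#' @param seed integer seed.
#' @return a [spectral_image()] with an all-`FALSE` mask.
#' @export
simulate_image <- function(model, shape = c(4, 12), gap_fraction = 0.05,
                           grid = wavenumber_grid(950, 1800, by = 3),
                           seed = 1L) {
  if (gap_fraction < 0 || gap_fraction > 1) stop("gap_fraction must be in [0, 1]")
  set.seed(seed)
  wn <- as.numeric(grid)
  nr <- 64L * shape[1]; nc <- 64L * shape[2]
  npix <- nr * nc
  prof <- deterministic_band_sum(model, wn)
  mult <- stats::rlnorm(npix, 0, max(model$spectrum_sigma, 1e-8))
  gaps <- sort(sample.int(npix, round(gap_fraction * npix)))
  mult[gaps] <- 0
  flat <- outer(mult, prof) +
    matrix(stats::rnorm(npix * length(wn), 0, max(model$noise_sd, 1e-4)),
           npix, length(wn))
  # gaps carry only faint detector noise, so amide-I stays below 0.01
  if (length(gaps))
    flat[gaps, ] <- matrix(stats::rnorm(length(gaps) * length(wn), 0, 1e-4),
                           length(gaps), length(wn))
  cube <- array(flat, c(nr, nc, length(wn)))
  img <- spectral_image(cube, wn, pixel_size_um = 175 / 64)
  attr(img, "gap_index") <- gaps
  img
}
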