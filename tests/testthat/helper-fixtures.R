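# Shared fixtures: tiny deterministic models and cohorts, all built in code.

# A single-band model with no randomness at all.
noise_free_model <- function(class = "normal", center = 1154, fwhm = 14,
                             amplitude = 0.5) {
  class_band_model(class, list(band_spec(center, fwhm, amplitude)),
                   patient_sigma = 0, spectrum_sigma = 0, noise_sd = 0,
                   baseline_offset_sd = 0, baseline_slope_sd = 0)
}

# Two classes differing only in one planted band at 1154 cm^-1.
planted_band_models <- function(delta = 0.10, noise_sd = 0.004,
                                patient_sigma = 0.05, spectrum_sigma = 0.05) {
  shared <- list(band_spec(1654, 45, 1.0), band_spec(1550, 38, 0.7),
                 band_spec(1240, 30, 0.15), band_spec(1080, 20, 0.15),
                 band_spec(1030, 30, 0.20))
  mk <- function(class, amp1154) {
    class_band_model(class, c(shared, list(band_spec(1154, 14, amp1154))),
                     patient_sigma = patient_sigma,
                     spectrum_sigma = spectrum_sigma,
                     noise_sd = noise_sd,
                     baseline_offset_sd = 0.002, baseline_slope_sd = 1e-6)
  }
  list(normal = mk("normal", 0.10 + delta), HCC = mk("HCC", 0.10))
}

# Small two-class cohort with a planted discriminative band.
planted_cohort <- function(seed = 1, n_patients = 8, n_spectra = 6,
                           delta = 0.10, ...) {
  design <- cohort_design(list(
    normal = list(n_patients = n_patients, samples_per_patient = 1,
                  spectra_per_sample = n_spectra),
    HCC = list(n_patients = n_patients, samples_per_patient = 1,
               spectra_per_sample = n_spectra)))
  simulate_cohort(design, planted_band_models(delta = delta, ...),
                  seed = seed)
}

# Cohort whose two "classes" are drawn from the identical model.
null_cohort <- function(seed = 1, n_patients = 8, n_spectra = 6) {
  models <- planted_band_models(delta = 0)
  models$normal <- class_band_model("normal", models$HCC$bands,
                                    patient_sigma = models$HCC$patient_sigma,
                                    spectrum_sigma = models$HCC$spectrum_sigma,
                                    noise_sd = models$HCC$noise_sd,
                                    baseline_offset_sd = 0.002,
                                    baseline_slope_sd = 1e-6)
  planted <- cohort_design(list(
    normal = list(n_patients = n_patients, samples_per_patient = 1,
                  spectra_per_sample = n_spectra),
    HCC = list(n_patients = n_patients, samples_per_patient = 1,
               spectra_per_sample = n_spectra)))
  simulate_cohort(planted, models, seed = seed)
}

# Preprocess a raw cohort down the classification path.
prep <- function(set) preprocess_chain(set)

# Tiny deterministic spectrum_set from a matrix.
tiny_set <- function(a, wn, classes = NULL, patients = NULL) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  n <- nrow(a)
  meta <- data.frame(
    patient_id = if (is.null(patients)) sprintf("P%d", seq_len(n)) else patients,
    sample_id = "S1", slice_id = 1L,
    class_label = if (is.null(classes)) rep("unknown", n) else classes)
  spectrum_set(a, wn, meta)
}

# Brute-force QDA posterior via direct density evaluation (no log tricks).
naive_qda_posterior <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  dens <- sapply(model$classes, function(k) {
    s <- model$covs[[k]]
    mu <- model$means[[k]]
    inv <- solve(s)
    apply(x, 1, function(v) {
      q <- as.numeric(t(v - mu) %*% inv %*% (v - mu))
      model$priors[[k]] * exp(-0.5 * q) /
        sqrt((2 * pi)^length(mu) * det(s))
    })
  })
  dens <- matrix(dens, nrow = nrow(x))
  dens / rowSums(dens)
}

# Random small feature data set for oracle checks.
random_feature_data <- function(n_per_class = 12, d = 3, n_classes = 2,
                                sep = 2) {
  x <- do.call(rbind, lapply(seq_len(n_classes), function(k)
    matrix(stats::rnorm(n_per_class * d, mean = sep * k), ncol = d)))
  labels <- rep(LETTERS[seq_len(n_classes)], each = n_per_class)
  list(x = x, labels = labels)
}
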