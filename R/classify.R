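#' Train a quadratic discriminant on a preprocessed spectrum set
#'
#' Convenience wrapper tying the discriminant to the region set and the
#' preprocessing signature it was trained under, so that scoring refuses
#' spectra preprocessed differently.
#'
#' @param train_set labelled, preprocessed [spectrum_set()].
#' @param regions a [region_set()].
#' @param lambda shrinkage for [qda_fit()].
#' @param priors optional named priors.
#' @return a [qda_fit()] model carrying `regions` and `norm_signature`.
#' @export
train_classifier <- function(train_set, regions, lambda = 1e-3,
                             priors = NULL) {
  x <- extract_features(train_set, regions)
  model <- qda_fit(x, train_set$meta$class_label, priors = priors,
                   lambda = lambda)
  model$regions <- regions
  model$norm_signature <- norm_signature(train_set)
  model
}

#' Classify tissue samples by mean posterior probability
#'
#' Scores every spectrum with the discriminant, then averages the
#' posterior vectors over each tissue sample (equal weight per spectrum,
#' grouped by patient and sample ID). The decision rules follow the
#' study protocol: for two classes a sample is assigned to the class
#' whose mean probability exceeds 0.5 (an exact 0.5 assigns tumor when a
#' tumor-like class is present — the clinically conservative choice — and
#' raises the `ambiguous` flag); with three or more classes the highest
#' mean probability wins, ties going to the class holding the highest
#' single-spectrum posterior, then to class order, again flagged.
#'
#' @param model a [train_classifier()] model.
#' @param set a [spectrum_set()] preprocessed identically to the
#'   training set (enforced via the preprocessing signature).
#' @return data frame of class `sample_classification` with one row per
#'   sample: `patient_id`, `sample_id`, `n_spectra`, `true_class`, one
#'   `P_<class>` column per class, `assigned_class`, `ambiguous`. The
#'   per-spectrum posterior matrix is attached as attribute `posteriors`.
#' @export
classify_samples <- function(model, set) {
  if (is.null(model$regions) || is.null(model$norm_signature))
    stop("model lacks region/normalization provenance; fit with train_classifier()")
  if (!identical(norm_signature(set), model$norm_signature))
    stop("preprocessing signature mismatch: model was trained under '",
         model$norm_signature, "' but the set is '", norm_signature(set), "'")
  x <- extract_features(set, model$regions)
  post <- qda_posterior(model, x)
  key <- interaction(set$meta$patient_id, set$meta$sample_id, drop = TRUE)
  groups <- split(seq_len(nrow(post)), key)
  classes <- model$classes
  rows <- lapply(groups, function(i) {
    mp <- colMeans(post[i, , drop = FALSE])
    dec <- decide_class(mp, post[i, , drop = FALSE], classes)
    truth <- unique(set$meta$class_label[i])
    data.frame(patient_id = set$meta$patient_id[i[1]],
               sample_id = set$meta$sample_id[i[1]],
               n_spectra = length(i),
               true_class = if (length(truth) == 1L) truth else NA_character_,
               t(mp),
               assigned_class = dec$class, ambiguous = dec$ambiguous,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) %in% classes] <- paste0("P_", classes)
  rownames(out) <- NULL
  out <- out[order(out$patient_id, out$sample_id), ]
  rownames(out) <- NULL
  attr(out, "posteriors") <- post
  attr(out, "classes") <- classes
  class(out) <- c("sample_classification", "data.frame")
  out
}

decide_class <- function(mean_p, post, classes) {
  if (length(classes) == 2L) {
    if (mean_p[1] == mean_p[2]) {        # exact tie at 0.5
      tum <- which(classes %in% c("tumor", "HCC", "CCC", "metastasis"))
      pick <- if (length(tum)) tum[1] else 1L
      return(list(class = classes[pick], ambiguous = TRUE))
    }
    return(list(class = classes[which.max(mean_p)], ambiguous = FALSE))
  }
  top <- which(mean_p == max(mean_p))
  if (length(top) == 1L)
    return(list(class = classes[top], ambiguous = FALSE))
  best_single <- apply(post[, top, drop = FALSE], 2, max)
  pick <- top[which.max(best_single)]    # which.max: first on ties = class order
  list(class = classes[pick], ambiguous = TRUE)
}

#' Probability-grid report of sample classifications
#'
#' Tabular counterpart of the study's probability-grid figures: one row
#' per sample with its patient ID, spectrum count, mean class
#' probabilities and per-spectrum assignments, plus a display color per
#' cell whose intensity is monotone in the posterior (white at 0 up to
#' the full class color at 1).
#'
#' @param results a [classify_samples()] result.
#' @param palette named class-color vector, default [class_palette()].
#' @param path optional CSV output path for the sample table.
#' @return list with `samples` (the result data frame plus the assigned
#'   class's display color) and `cells` (long data frame: one row per
#'   spectrum with its top class, posterior and color).
#' @export
render_probability_grid <- function(results, palette = class_palette(),
                                    path = NULL) {
  stopifnot(inherits(results, "sample_classification"), nrow(results) > 0)
  classes <- attr(results, "classes")
  post <- attr(results, "posteriors")
  samples <- as.data.frame(results)
  samples$color <- vapply(seq_len(nrow(samples)), function(i) {
    cl <- samples$assigned_class[i]
    probability_color(samples[[paste0("P_", cl)]][i], palette[[cl]])
  }, character(1))
  top <- max.col(post, ties.method = "first")
  cells <- data.frame(spectrum = seq_len(nrow(post)),
                      top_class = classes[top],
                      posterior = post[cbind(seq_len(nrow(post)), top)])
  cells$color <- mapply(probability_color, cells$posterior,
                        palette[cells$top_class])
  if (!is.null(path)) utils::write.csv(samples, path, row.names = FALSE)
  list(samples = samples, cells = cells)
}

# Linear mix from white (p = 0) to the class color (p = 1).
probability_color <- function(p, color) {
  stopifnot(p >= 0, p <= 1)
  rgb_t <- grDevices::col2rgb(color)[, 1]
  mixed <- round(255 * (1 - p) + rgb_t * p)
  grDevices::rgb(mixed[1], mixed[2], mixed[3], maxColorValue = 255)
}
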