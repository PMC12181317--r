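#' Fit a quadratic discriminant model
#'
#' Class-conditional Gaussian classifier with one mean vector and one
#' covariance matrix per class. Covariances are the class sample
#' covariances (n-1 denominator) with trace-scaled ridge shrinkage,
#' `S_k + lambda * (tr(S_k)/d) * I`, which keeps narrow-window feature
#' sets well conditioned; priors default to the empirical class
#' frequencies.
#'
#' @param x numeric feature matrix, one row per spectrum.
#' @param labels class label per row (at least two spectra per class).
#' @param priors optional named prior vector (normalized internally).
#' @param lambda shrinkage strength (default `1e-3`); the model records
#'   the value used.
#' @return object of class `qda_model` with fields `classes`, `means`,
#'   `covs`, `priors`, `lambda` (plus the Cholesky factors used for
#'   scoring).
#' @export
qda_fit <- function(x, labels, priors = NULL, lambda = 1e-3) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), lambda >= 0)
  classes <- sort(unique(labels))
  d <- ncol(x)
  counts <- table(factor(labels, classes))
  if (any(counts < 2L))
    stop("need at least 2 spectra per class; class '",
         names(counts)[which(counts < 2)[1]], "' has ",
         min(counts))
  if (is.null(priors)) {
    priors <- as.numeric(counts) / length(labels)
    names(priors) <- classes
  } else {
    priors <- priors[classes] / sum(priors[classes])
  }
  means <- covs <- chols <- vector("list", length(classes))
  names(means) <- names(covs) <- names(chols) <- classes
  for (k in classes) {
    xi <- x[labels == k, , drop = FALSE]
    means[[k]] <- colMeans(xi)
    s <- stats::cov(xi)
    scale <- sum(diag(s)) / d
    if (scale <= 0) scale <- 1        # fully degenerate class: plain ridge
    s <- s + lambda * scale * diag(d)
    ch <- tryCatch(chol(s), error = function(e) NULL)
    if (is.null(ch))
      stop("class covariance singular after shrinkage; increase lambda ",
           "(class '", k, "')")
    covs[[k]] <- s
    chols[[k]] <- ch
  }
  structure(list(classes = classes, means = means, covs = covs,
                 priors = priors, lambda = lambda, d = d,
                 chols = chols, regions = NULL, norm_signature = NULL),
            class = "qda_model")
}

#' @export
print.qda_model <- function(x, ...) {
  cat(sprintf("qda_model: %d classes (%s), %d features, lambda = %g\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              x$d, x$lambda))
  invisible(x)
}

#' Posterior class probabilities under a quadratic discriminant
#'
#' `posterior_k proportional to prior_k * N(x; mu_k, Sigma_k)`, evaluated
#' in log space and normalized with log-sum-exp, so each returned row sums
#' to 1 even for very peaked likelihoods.
#'
#' @param model a [qda_model()].
#' @param x feature matrix (or single vector) with `model$d` columns; all
#'   values must be finite.
#' @return matrix of posteriors, one row per input, columns in
#'   `model$classes` order.
#' @export
qda_posterior <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$d)
    stop("feature dimension ", ncol(x), " does not match model (", model$d, ")")
  if (!all(is.finite(x))) stop("non-finite feature values")
  n <- nrow(x)
  logd <- matrix(NA_real_, n, length(model$classes),
                 dimnames = list(NULL, model$classes))
  for (k in model$classes) {
    ch <- model$chols[[k]]
    centered <- sweep(x, 2, model$means[[k]])
    z <- backsolve(ch, t(centered), transpose = TRUE)   # solves t(ch) %*% z = t(centered)
    quad <- colSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    logd[, k] <- log(model$priors[[k]]) -
      0.5 * (model$d * log(2 * pi) + logdet + quad)
  }
  mx <- apply(logd, 1, max)
  p <- exp(logd - mx)
  p / rowSums(p)
}

#' Hard class prediction (argmax posterior)
#' @param model a [qda_model()].
#' @param x feature matrix.
#' @return character vector of class labels.
#' @export
qda_predict <- function(model, x) {
  p <- qda_posterior(model, x)
  model$classes[max.col(p, ties.method = "first")]
}

#' Stratified k-fold cross-validation of the discriminant
#'
#' Splits the set into k stratified folds at the chosen level, fits the
#' discriminant on each training portion over the region features and
#' predicts the held-out fold, so every spectrum is predicted exactly
#' once. Patient-level folding keeps all of a patient's spectra in one
#' fold (stratification then applies to patients within class).
#'
#' @param set labelled, preprocessed [spectrum_set()].
#' @param regions a [region_set()].
#' @param k number of folds (default 10).
#' @param split_level `"spectrum"` or `"patient"`.
#' @param seed integer seed for the fold draw.
#' @param lambda shrinkage for [qda_fit()].
#' @return list with `pooled_accuracy`, `fold_accuracy`, and the
#'   per-spectrum `predicted` labels.
#' @export
kfold_cross_validate <- function(set, regions, k = 10,
                                 split_level = c("spectrum", "patient"),
                                 seed = 1L, lambda = 1e-3) {
  split_level <- match.arg(split_level)
  stopifnot(k >= 2)
  lab <- set$meta$class_label
  n <- n_spectra(set)
  set.seed(seed)
  fold <- integer(n)
  if (split_level == "spectrum") {
    if (k > n) stop("k exceeds the number of spectra")
    # cyclic assignment over class-grouped shuffled spectra: folds are
    # balanced and approximately stratified; k = n gives leave-one-out
    ord <- unlist(lapply(unique(lab), function(cl) sample(which(lab == cl))))
    fold[ord] <- rep_len(seq_len(k), n)
  } else {
    pats_by_class <- lapply(unique(lab), function(cl)
      sample(unique(set$meta$patient_id[lab == cl])))
    pats <- unlist(pats_by_class)
    if (k > length(pats)) stop("k exceeds the number of patients")
    pf <- rep_len(seq_len(k), length(pats))
    for (j in seq_along(pats)) fold[set$meta$patient_id == pats[j]] <- pf[j]
  }
  x <- extract_features(set, regions)
  predicted <- character(n)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    hold <- fold == f
    m <- qda_fit(x[!hold, , drop = FALSE], lab[!hold], lambda = lambda)
    predicted[hold] <- qda_predict(m, x[hold, , drop = FALSE])
    fold_acc[f] <- mean(predicted[hold] == lab[hold])
  }
  list(pooled_accuracy = mean(predicted == lab),
       fold_accuracy = fold_acc, predicted = predicted, fold = fold)
}
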