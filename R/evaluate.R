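#' Sample-level confusion matrix
#'
#' Rows are the predicted ("classified as") classes and columns the true
#' classes, so each column sums to the number of samples truly in that
#' class.
#'
#' @param predicted character vector of assigned classes, or a
#'   [classify_samples()] result (then `truth` defaults to its
#'   `true_class` column).
#' @param truth character vector of true classes, same length.
#' @param classes optional class order; defaults to the sorted union.
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(predicted, truth = NULL, classes = NULL) {
  if (inherits(predicted, "sample_classification")) {
    if (is.null(truth)) truth <- predicted$true_class
    predicted <- predicted$assigned_class
  }
  if (is.null(truth)) stop("truth labels are required")
  stopifnot(length(predicted) == length(truth))
  if (anyNA(truth)) stop("unknown truth label (NA)")
  if (is.null(classes)) classes <- sort(unique(c(predicted, truth)))
  bad <- setdiff(truth, classes)
  if (length(bad)) stop("unknown truth label: ", bad[1])
  cm <- table(factor(predicted, classes), factor(truth, classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(predicted = classes, true = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Build a confusion matrix from counts
#'
#' For worked examples and published tables: `counts` is given row-major
#' in the stated class order (rows = classified as, columns = true).
#'
#' @param counts numeric vector of length `length(classes)^2`, row-major.
#' @param classes class labels in table order.
#' @export
confusion_from_counts <- function(counts, classes) {
  k <- length(classes)
  stopifnot(length(counts) == k * k, all(counts >= 0),
            all(counts == round(counts)))
  m <- matrix(as.integer(counts), nrow = k, byrow = TRUE,
              dimnames = list(predicted = classes, true = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy of any confusion matrix
#' @param cm a [confusion_matrix()].
#' @return `trace / total`.
#' @export
overall_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Binary classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)` and
#' `F1 = 2*precision*sensitivity/(precision+sensitivity)`, with the
#' stated class as positive. A metric with a zero denominator is reported
#' as `NA` (undefined), never as 0. Values are returned at full
#' precision; `round_metrics()` gives the 2-decimal report form.
#'
#' @param cm a 2x2 [confusion_matrix()].
#' @param positive_class name of the positive class (for tissue screening
#'   the tumor class).
#' @return named numeric vector.
#' @export
binary_metrics <- function(cm, positive_class) {
  stopifnot(inherits(cm, "confusion_matrix"), all(dim(cm) == c(2, 2)))
  classes <- rownames(cm)
  if (!positive_class %in% classes)
    stop("positive class '", positive_class, "' not in matrix")
  pos <- positive_class
  neg <- setdiff(classes, pos)
  tp <- cm[pos, pos]; fn <- cm[neg, pos]
  tn <- cm[neg, neg]; fp <- cm[pos, neg]
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  c(sensitivity = sens, specificity = spec, accuracy = acc,
    f1 = f1, precision = prec)
}

#' @rdname binary_metrics
#' @param metrics a metric vector from [binary_metrics()].
#' @param digits decimals for reporting (default 2).
#' @export
round_metrics <- function(metrics, digits = 2) round(metrics, digits)

#' t-test configuration
#'
#' @param alpha significance level (default 0.05).
#' @param variant `"pooled"` (equal-variance two-sample t, the default)
#'   or `"welch"`.
#' @param correction `"none"` (default) or `"benjamini_hochberg"`.
#' @export
ttest_config <- function(alpha = 0.05, variant = c("pooled", "welch"),
                         correction = c("none", "benjamini_hochberg")) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, variant = match.arg(variant),
                 correction = match.arg(correction)),
            class = "ttest_config")
}

#' Per-wavenumber two-sample t-tests
#'
#' Tests, at every grid point, whether the absorbances of two groups of
#' area-normalized spectra share a mean. The default is the pooled
#' (equal-variance) two-sample t statistic; Welch's variant and
#' Benjamini-Hochberg correction are available by configuration. A point
#' where the pooled variance is zero is degenerate: p is reported as 0
#' when the group means differ and 1 when they are equal, and the
#' `degenerate` flag is set.
#'
#' @param setA,setB [spectrum_set()]s on the same grid, each with at
#'   least 2 spectra.
#' @param config a [ttest_config()].
#' @return data frame: `wavenumber`, `t`, `df`, `p`, `significant`,
#'   `degenerate`.
#' @export
ttest_per_wavenumber <- function(setA, setB, config = ttest_config()) {
  stopifnot(inherits(setA, "spectrum_set"), inherits(setB, "spectrum_set"))
  if (!isTRUE(all.equal(setA$wavenumbers, setB$wavenumbers)))
    stop("the two sets must share one wavenumber grid")
  a <- setA$absorbance; b <- setB$absorbance
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 spectra")
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  if (config$variant == "pooled") {
    df <- rep(na + nb - 2, length(ma))
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degenerate <- se == 0 | !is.finite(se)
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  t[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 0, Inf * sign(ma - mb)[degenerate])
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  p_adj <- if (config$correction == "benjamini_hochberg")
    stats::p.adjust(p, "BH") else p
  data.frame(wavenumber = setA$wavenumbers, t = t, df = df, p = p,
             p_adjusted = p_adj,
             significant = p_adj < config$alpha,
             degenerate = degenerate)
}
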