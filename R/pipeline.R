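#' Experiment configuration
#'
#' Describes one full classification experiment, binary (normal vs the
#' pooled tumor class) or three-class (metastasis vs CCC vs HCC), from a
#' labelled cohort to evaluation. Training and test sets are partitioned
#' at patient level: a patient contributes all of their spectra to one
#' side, never both. The binary task draws 20 training patients
#' (balanced 10 normal + 10 tumor by default); the three-class task draws
#' 6 training patients per entity.
#'
#' @param task `"binary"` or `"three_class"`.
#' @param n_train_patients named integer vector of training patients per
#'   class; defaults per task as above.
#' @param preprocess a [preprocess_spec()].
#' @param regions `NULL` to run the genetic selector, or a fixed
#'   [region_set()] (e.g. [preset_regions()]).
#' @param ga a [ga_config()] (used when `regions` is `NULL`).
#' @param k cross-validation folds (default 10).
#' @param lambda discriminant shrinkage.
#' @param seed integer seed driving every random draw of the experiment.
#' @export
experiment_config <- function(task = c("binary", "three_class"),
                              n_train_patients = NULL,
                              preprocess = preprocess_spec(),
                              regions = NULL, ga = ga_config(),
                              k = 10, lambda = 1e-3, seed = 1L) {
  task <- match.arg(task)
  if (is.null(n_train_patients)) {
    n_train_patients <- if (task == "binary") c(normal = 10, tumor = 10)
      else c(metastasis = 6, CCC = 6, HCC = 6)
  }
  structure(list(task = task, n_train_patients = n_train_patients,
                 preprocess = preprocess, regions = regions, ga = ga,
                 k = k, lambda = lambda, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a full classification experiment
#'
#' The protocol: (1) relabel to the task's classes (tumor union for the
#' binary task); (2) preprocess the whole cohort with the fixed chain;
#' (3) draw the patient-level training partition; (4) select regions with
#' the genetic routine on the training set only (or take the configured
#' preset); (5) fit the quadratic discriminant on the training spectra;
#' (6) re-classify the training samples, run k-fold cross-validation, and
#' classify the independent test samples; (7) evaluate both sides with
#' confusion matrices and metrics. Every random draw is consumed from the
#' experiment seed, so identical configs give identical reports; regions
#' and model derive from training data only.
#'
#' @param config an [experiment_config()].
#' @param data a raw labelled [spectrum_set()] (entity labels
#'   normal/HCC/CCC/metastasis).
#' @param water_reference forwarded to [preprocess_chain()] when
#'   atmospheric compensation is enabled.
#' @return list of class `ir_experiment`: config, train/test patient IDs,
#'   `regions`, `model`, `train` and `test` (each with sample results,
#'   confusion matrix and metrics), and `cv`.
#' @export
run_experiment <- function(config, data, water_reference = NULL) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(data, "spectrum_set"))
  if (config$task == "binary") data <- relabel_to_tumor_union(data)
  labs <- data$meta$class_label
  need <- names(config$n_train_patients)
  missing_cl <- setdiff(need, unique(labs))
  if (length(missing_cl))
    stop("class missing from the data: ", missing_cl[1])

  pre <- preprocess_chain(data, config$preprocess, water_reference)

  set.seed(config$seed)
  train_pat <- unlist(lapply(need, function(cl) {
    pats <- unique(pre$meta$patient_id[pre$meta$class_label == cl])
    n <- config$n_train_patients[[cl]]
    if (n >= length(pats))
      stop("not enough patients in class ", cl, " to hold out a test set")
    sample(pats, n)
  }))
  in_train <- pre$meta$patient_id %in% train_pat
  train <- subset_spectra(pre, in_train)
  test <- subset_spectra(pre, !in_train)

  regions <- config$regions
  if (is.null(regions)) {
    ga <- config$ga
    ga$seed <- config$seed + 1L      # dedicated stream for the selector
    regions <- ga_select_regions(train, ga)
  }

  model <- train_classifier(train, regions, lambda = config$lambda)

  cv <- kfold_cross_validate(train, regions, k = config$k,
                             seed = config$seed + 2L,
                             lambda = config$lambda)

  evaluate_side <- function(set) {
    res <- classify_samples(model, set)
    cm <- confusion_matrix(res, classes = model$classes)
    metrics <- if (length(model$classes) == 2L) {
      pos <- intersect(c("tumor", "HCC", "CCC", "metastasis"), model$classes)
      binary_metrics(cm, if (length(pos)) pos[1] else model$classes[2])
    } else c(accuracy = overall_accuracy(cm))
    list(samples = res, confusion = cm, metrics = metrics)
  }

  structure(list(config = config, seed = config$seed,
                 train_patients = sort(train_pat),
                 test_patients = sort(setdiff(unique(pre$meta$patient_id),
                                              train_pat)),
                 n_train_spectra = n_spectra(train),
                 n_test_spectra = n_spectra(test),
                 regions = regions, model = model, cv = cv,
                 train = evaluate_side(train),
                 test = evaluate_side(test)),
            class = "ir_experiment")
}

#' @export
print.ir_experiment <- function(x, ...) {
  cat(sprintf("ir_experiment (%s): %d train / %d test spectra, %d/%d patients\n",
              x$config$task, x$n_train_spectra, x$n_test_spectra,
              length(x$train_patients), length(x$test_patients)))
  print(x$regions)
  cat(sprintf("  CV pooled accuracy (k=%d): %.3f\n", x$config$k,
              x$cv$pooled_accuracy))
  cat("  test metrics:\n")
  print(round(x$test$metrics, 3))
  invisible(x)
}
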