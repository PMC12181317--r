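#' Sets of discriminative wavenumber windows
#'
#' A `region_set` holds the spectral windows a classifier reads its
#' features from: closed intervals `[lo, hi]` in cm^-1 inside the
#' classification range. On construction the windows are clipped to the
#' limits, sorted by lower edge and merged when they overlap or touch, so
#' every emitted set is in canonical form and the repair is idempotent.
#'
#' @param windows numeric matrix (or 2-vector) with columns `lo`, `hi`.
#' @param limits allowed range, default `c(950, 1480)`.
#' @param fitness optional held-out accuracy recorded as provenance.
#' @param config_hash optional provenance string for the selector config.
#' @return object of class `region_set`.
#' @export
region_set <- function(windows, limits = c(950, 1480), fitness = NA_real_,
                       config_hash = NA_character_) {
  if (is.vector(windows)) windows <- matrix(windows, ncol = 2, byrow = TRUE)
  windows <- as.matrix(windows)
  if (ncol(windows) != 2L) stop("windows must have two columns (lo, hi)")
  if (nrow(windows) < 1L) stop("need at least one window")
  windows[, 1] <- pmax(windows[, 1], limits[1])
  windows[, 2] <- pmin(windows[, 2], limits[2])
  if (any(windows[, 1] >= windows[, 2]))
    stop("every window needs lo < hi inside [", limits[1], ", ", limits[2], "]")
  windows <- windows[order(windows[, 1]), , drop = FALSE]
  merged <- windows[1, , drop = FALSE]
  if (nrow(windows) > 1) for (i in 2:nrow(windows)) {
    last <- nrow(merged)
    if (windows[i, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], windows[i, 2])
    } else {
      merged <- rbind(merged, windows[i, , drop = FALSE])
    }
  }
  dimnames(merged) <- list(NULL, c("lo", "hi"))
  structure(list(windows = merged, limits = limits, fitness = fitness,
                 config_hash = config_hash),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:",
      paste(sprintf("[%g, %g]", x$windows[, 1], x$windows[, 2]), collapse = " "),
      "cm^-1\n")
  if (!is.na(x$fitness)) cat("  held-out fitness:", round(x$fitness, 4), "\n")
  invisible(x)
}

#' Reference region sets of the liver-tissue study
#'
#' The wavenumber windows reported as optimal for the two classification
#' tasks, shipped as presets so classification can be run without the
#' genetic selector. `"normal_vs_tumor"`: 995--1005, 1102--1114 and
#' 1151--1155 cm^-1 (water content plus two glycogen regions).
#' `"tumor_entities"`: 968--972 and 1252--1258 cm^-1 plus the single
#' frequencies 1396 and 1450 cm^-1, represented here as +/-2 cm^-1
#' windows so each contains grid points at any standard spacing.
#'
#' @param task `"normal_vs_tumor"` or `"tumor_entities"`.
#' @return a [region_set()].
#' @export
preset_regions <- function(task = c("normal_vs_tumor", "tumor_entities")) {
  task <- match.arg(task)
  w <- switch(task,
    normal_vs_tumor = rbind(c(995, 1005), c(1102, 1114), c(1151, 1155)),
    tumor_entities = rbind(c(968, 972), c(1252, 1258), c(1394, 1398),
                           c(1448, 1452)))
  region_set(w, config_hash = paste0("preset:", task))
}

#' Extract the feature table a region set defines
#'
#' Each spectrum is re-expressed as the series of its absorbance values at
#' every grid point inside each window, window order then wavenumber
#' order. Column names carry the wavenumbers.
#'
#' @param set a preprocessed [spectrum_set()].
#' @param regions a [region_set()].
#' @return numeric matrix, one row per spectrum.
#' @export
extract_features <- function(set, regions) {
  stopifnot(inherits(set, "spectrum_set"), inherits(regions, "region_set"))
  idx <- integer(0)
  for (i in seq_len(nrow(regions$windows))) {
    w <- regions$windows[i, ]
    j <- window_indices(set$wavenumbers, w[1], w[2])
    if (!length(j))
      stop(sprintf("window [%g, %g] contains no grid point", w[1], w[2]))
    idx <- c(idx, j)
  }
  x <- set$absorbance[, idx, drop = FALSE]
  colnames(x) <- sprintf("wn%g", set$wavenumbers[idx])
  x
}

#' Genetic-selector configuration
#'
#' Hyperparameters of the genetic routine that searches for discriminative
#' wavenumber windows. The chromosome is a fixed-length list of
#' `(center, width)` genes with an on/off bit each; selection is
#' tournament (size 3), crossover exchanges whole genes uniformly,
#' mutation jitters centers and widths with Gaussian noise (clipped to the
#' classification range) and flips bits; elitism carries the best
#' candidates over unchanged. Fitness is the held-out accuracy of a
#' quadratic discriminant fitted on 65% of the training spectra and scored
#' on the remaining 35%; the split is drawn once per run from the seed and
#' reused for every candidate.
#'
#' @param n_windows allowed range of active windows, default `c(2, 5)`.
#' @param width_range window width range in cm^-1, default `c(4, 40)`.
#' @param pop_size population size (default 60).
#' @param generations number of generations (default 80).
#' @param p_crossover crossover probability per mating pair (default 0.7).
#' @param p_mutation mutation probability per gene (default 0.1).
#' @param elitism number of elite candidates preserved (default 2).
#' @param split_fraction fraction of training spectra used to fit the
#'   discriminant; the rest scores it (default 0.65).
#' @param split_level `"spectrum"` (default) or `"patient"`.
#'   Spectrum-level splitting follows the historical protocol; patient-
#'   level splitting avoids leaking patient effects and is recommended.
#' @param lambda shrinkage passed to [qda_fit()].
#' @param seed integer seed for the whole run.
#' @export
ga_config <- function(n_windows = c(2, 5), width_range = c(4, 40),
                      pop_size = 60, generations = 80, p_crossover = 0.7,
                      p_mutation = 0.1, elitism = 2, split_fraction = 0.65,
                      split_level = c("spectrum", "patient"),
                      lambda = 1e-3, seed = 1L) {
  split_level <- match.arg(split_level)
  stopifnot(pop_size >= 1, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            split_fraction > 0, split_fraction < 1,
            n_windows[1] >= 1, n_windows[2] >= n_windows[1],
            width_range[1] > 0, width_range[2] >= width_range[1],
            elitism >= 0)
  structure(list(n_windows = n_windows, width_range = width_range,
                 pop_size = pop_size, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = elitism, split_fraction = split_fraction,
                 split_level = split_level, lambda = lambda, seed = seed),
            class = "ga_config")
}

config_hash <- function(config) {
  paste0("ga:", paste(unlist(config), collapse = ","))
}

# Stratified 65/35 split; returns logical "in fitting portion" per spectrum.
ga_split <- function(set, config) {
  lab <- set$meta$class_label
  fit_idx <- logical(n_spectra(set))
  if (config$split_level == "spectrum") {
    for (cl in unique(lab)) {
      i <- which(lab == cl)
      n_fit <- max(1L, round(config$split_fraction * length(i)))
      fit_idx[sample(i, n_fit)] <- TRUE
    }
  } else {
    for (cl in unique(lab)) {
      pats <- unique(set$meta$patient_id[lab == cl])
      n_fit <- max(1L, round(config$split_fraction * length(pats)))
      keep <- sample(pats, n_fit)
      fit_idx[lab == cl & set$meta$patient_id %in% keep] <- TRUE
    }
  }
  fit_idx
}

#' Fitness of a candidate region set
#'
#' Fits a quadratic discriminant on the 65% portion of the training set
#' over the candidate's features and returns the spectrum-level accuracy
#' on the held-out 35%. A candidate whose fitting portion lacks a class
#' (or whose discriminant cannot be fitted) scores 0 with a warning.
#'
#' @param regions a [region_set()].
#' @param train_set labelled, preprocessed [spectrum_set()].
#' @param config a [ga_config()].
#' @param split optional logical vector (TRUE = fitting portion); drawn
#'   from the config seed when omitted.
#' @return accuracy in `[0, 1]`.
#' @export
region_fitness <- function(regions, train_set, config = ga_config(),
                           split = NULL) {
  if (is.null(split)) {
    set.seed(config$seed)
    split <- ga_split(train_set, config)
  }
  x <- extract_features(train_set, regions)
  lab <- train_set$meta$class_label
  if (length(unique(lab[split])) < length(unique(lab))) {
    warning("a class is absent from the fitting portion; candidate scored 0")
    return(0)
  }
  model <- tryCatch(
    qda_fit(x[split, , drop = FALSE], lab[split], lambda = config$lambda),
    error = function(e) NULL)
  if (is.null(model)) {
    warning("discriminant fit failed; candidate scored 0")
    return(0)
  }
  pred <- qda_predict(model, x[!split, , drop = FALSE])
  mean(pred == lab[!split])
}

# --- GA internals -----------------------------------------------------------
# A chromosome is a list(center, width, on): numeric vectors of length
# n_windows[2]. Repair clips genes and enforces the active-window count.

ga_random_chromosome <- function(config, limits) {
  m <- config$n_windows[2]
  chr <- list(center = stats::runif(m, limits[1], limits[2]),
              width = stats::runif(m, config$width_range[1],
                                   config$width_range[2]),
              on = stats::runif(m) < 0.5)
  ga_repair(chr, config, limits)
}

ga_repair <- function(chr, config, limits) {
  chr$width <- pmin(pmax(chr$width, config$width_range[1]),
                    config$width_range[2])
  chr$center <- pmin(pmax(chr$center, limits[1]), limits[2])
  n_on <- sum(chr$on)
  if (n_on < config$n_windows[1]) {
    off <- which(!chr$on)
    chr$on[sample_safe(off, config$n_windows[1] - n_on)] <- TRUE
  } else if (n_on > config$n_windows[2]) {
    on <- which(chr$on)
    chr$on[sample_safe(on, n_on - config$n_windows[2])] <- FALSE
  }
  chr
}

sample_safe <- function(x, n) if (length(x) == 1L) x else sample(x, n)

ga_decode <- function(chr, limits, wn) {
  i <- which(chr$on)
  lo <- pmax(chr$center[i] - chr$width[i] / 2, limits[1])
  hi <- pmin(chr$center[i] + chr$width[i] / 2, limits[2])
  # guarantee at least one grid point per window
  step <- grid_spacing(wn)
  hi <- pmax(hi, lo + step)
  region_set(cbind(lo, hi), limits)
}

ga_mutate <- function(chr, config, limits) {
  m <- length(chr$center)
  hit <- stats::runif(m) < config$p_mutation
  chr$center[hit] <- chr$center[hit] + stats::rnorm(sum(hit), 0, 10)
  hit <- stats::runif(m) < config$p_mutation
  chr$width[hit] <- chr$width[hit] + stats::rnorm(sum(hit), 0, 4)
  hit <- stats::runif(m) < config$p_mutation
  chr$on[hit] <- !chr$on[hit]
  ga_repair(chr, config, limits)
}

ga_crossover <- function(a, b, config) {
  if (stats::runif(1) >= config$p_crossover) return(list(a, b))
  m <- length(a$center)
  swap <- stats::runif(m) < 0.5      # uniform exchange of whole genes
  for (f in c("center", "width", "on")) {
    tmp <- a[[f]][swap]; a[[f]][swap] <- b[[f]][swap]; b[[f]][swap] <- tmp
  }
  list(a, b)
}

n_region_features <- function(regions, wn) {
  sum(vapply(seq_len(nrow(regions$windows)), function(i)
    length(window_indices(wn, regions$windows[i, 1], regions$windows[i, 2])),
    integer(1)))
}

# TRUE if candidate a beats b: higher fitness; ties broken by fewer
# features, then lower mean wavenumber (reproducible runs).
ga_better <- function(fa, ra, fb, rb, wn) {
  if (fa != fb) return(fa > fb)
  na <- n_region_features(ra, wn); nb <- n_region_features(rb, wn)
  if (na != nb) return(na < nb)
  mean(ra$windows) < mean(rb$windows)
}

#' Genetic selection of discriminative spectral regions
#'
#' Runs the genetic routine of [ga_config()] on a labelled training set
#' and returns the best region set found, with its held-out fitness and a
#' config hash recorded as provenance. With elitism the best fitness is
#' non-decreasing over generations; identical seeds give identical
#' results.
#'
#' @param train_set labelled, preprocessed [spectrum_set()] (at least two
#'   classes).
#' @param config a [ga_config()].
#' @return a [region_set()].
#' @export
ga_select_regions <- function(train_set, config = ga_config()) {
  stopifnot(inherits(train_set, "spectrum_set"), inherits(config, "ga_config"))
  if (length(unique(train_set$meta$class_label)) < 2L)
    stop("region selection needs at least two classes")
  limits <- c(max(950, min(train_set$wavenumbers)),
              min(1480, max(train_set$wavenumbers)))
  wn <- train_set$wavenumbers
  set.seed(config$seed)
  split <- ga_split(train_set, config)

  score <- function(chr) {
    regions <- ga_decode(chr, limits, wn)
    suppressWarnings(region_fitness(regions, train_set, config, split))
  }
  pop <- lapply(seq_len(config$pop_size), function(i)
    ga_random_chromosome(config, limits))
  fit <- vapply(pop, score, numeric(1))

  best_chr <- NULL; best_fit <- -Inf; best_reg <- NULL
  note_best <- function() {
    for (i in seq_along(pop)) {
      ri <- ga_decode(pop[[i]], limits, wn)
      if (is.null(best_reg) ||
          ga_better(fit[i], ri, best_fit, best_reg, wn)) {
        best_chr <<- pop[[i]]; best_fit <<- fit[i]; best_reg <<- ri
      }
    }
  }
  note_best()

  for (g in seq_len(config$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(min(config$elitism, length(pop)))]]
    children <- list()
    while (length(children) < config$pop_size - length(elite)) {
      pa <- ga_tournament(fit); pb <- ga_tournament(fit)
      off <- ga_crossover(pop[[pa]], pop[[pb]], config)
      off <- lapply(off, ga_mutate, config = config, limits = limits)
      children <- c(children, off)
    }
    pop <- c(elite, children[seq_len(config$pop_size - length(elite))])
    fit <- vapply(pop, score, numeric(1))
    note_best()
  }
  best_reg$fitness <- best_fit
  best_reg$config_hash <- config_hash(config)
  best_reg
}

ga_tournament <- function(fit, size = 3L) {
  cand <- sample.int(length(fit), min(size, length(fit)), replace = TRUE)
  cand[which.max(fit[cand])]
}
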