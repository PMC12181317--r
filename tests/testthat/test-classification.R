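test_that("qda_fit recovers textbook means, covariances and priors", {
  x <- matrix(c(-1, -1, 1, 1), ncol = 1)
  m <- qda_fit(x, c("A", "A", "B", "B"))
  expect_equal(m$means$A, -1, ignore_attr = TRUE)
  expect_equal(m$means$B, 1, ignore_attr = TRUE)
  expect_equal(as.numeric(m$priors), c(0.5, 0.5))

  set.seed(17)
  for (rep in 1:5) {
    d <- random_feature_data(n_per_class = 10, d = 3)
    m <- qda_fit(d$x, d$labels, lambda = 0)
    for (k in c("A", "B")) {
      xi <- d$x[d$labels == k, ]
      # brute-force covariance: sum of outer products / (n - 1)
      mu <- colMeans(xi)
      s <- Reduce(`+`, lapply(seq_len(nrow(xi)), function(i)
        tcrossprod(xi[i, ] - mu))) / (nrow(xi) - 1)
      expect_equal(m$covs[[k]], s, tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
  expect_error(qda_fit(matrix(1:3, ncol = 1), c("A", "A", "B")),
               "at least 2 spectra")
  # identical degenerate classes: singular covariance is reported as such
  xx <- matrix(c(1, 1, 1, 1), ncol = 1)
  expect_error(qda_fit(xx, c("A", "A", "B", "B"), lambda = 0), "singular")
})

test_that("posteriors match closed forms and sum to one", {
  x <- matrix(c(-1, 0, -2, 1, 0, 2), ncol = 1)
  m <- qda_fit(x, rep(c("A", "B"), each = 3), lambda = 0)
  # symmetric setup: x = 0 is equivocal
  expect_equal(as.numeric(qda_posterior(m, 0)), c(0.5, 0.5), tolerance = 1e-9)

  # mu_A = 0, mu_B = 2, sigma^2 = 1, equal priors, x = 0.5:
  # log-likelihood ratio = 1, P(A) = 1/(1 + exp(-1))
  mA <- list(classes = c("A", "B"),
             means = list(A = 0, B = 2),
             covs = list(A = matrix(1), B = matrix(1)),
             chols = list(A = matrix(1), B = matrix(1)),
             priors = c(A = 0.5, B = 0.5), lambda = 0, d = 1)
  class(mA) <- "qda_model"
  expect_equal(qda_posterior(mA, 0.5)[1, "A"], 1 / (1 + exp(-1)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # equal data in both classes scores the priors everywhere
  set.seed(18)
  xi <- matrix(stats::rnorm(12), ncol = 2)
  m2 <- qda_fit(rbind(xi, xi), rep(c("A", "B"), each = 6),
                priors = c(A = 0.3, B = 0.7))
  p <- qda_posterior(m2, c(0.2, -0.4))
  expect_equal(as.numeric(p), c(0.3, 0.7), tolerance = 1e-9)
  expect_error(qda_posterior(m2, c(NA, 1)), "finite")
  expect_error(qda_posterior(m2, c(1, 2, 3)), "dimension")
})

test_that("log-space posteriors equal naive density ratios and MASS::qda", {
  set.seed(19)
  for (rep in 1:10) {
    d <- random_feature_data(n_per_class = 15, d = 3,
                             n_classes = sample(2:3, 1))
    m <- qda_fit(d$x, d$labels, lambda = 1e-3)
    xt <- matrix(stats::rnorm(15, mean = 2), ncol = 3)
    expect_equal(qda_posterior(m, xt), naive_qda_posterior(m, xt),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  skip_if_not_installed("MASS")
  d <- random_feature_data(n_per_class = 25, d = 3)
  m <- qda_fit(d$x, d$labels, lambda = 0)
  ref <- MASS::qda(d$x, grouping = d$labels)
  xt <- matrix(stats::rnorm(30, mean = 2.5), ncol = 3)
  expect_equal(qda_posterior(m, xt),
               stats::predict(ref, xt)$posterior,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("cross-validation predicts each spectrum once; LOO matches a loop", {
  sep <- prep(planted_cohort(seed = 20, n_patients = 6, n_spectra = 4,
                             delta = 0.5, noise_sd = 1e-4,
                             patient_sigma = 0, spectrum_sigma = 0.01))
  regions <- region_set(c(1140, 1170))
  for (k in c(2, 4)) {
    cv <- kfold_cross_validate(sep, regions, k = k, seed = 1)
    expect_equal(cv$pooled_accuracy, 1.0)
    expect_equal(length(cv$predicted), n_spectra(sep))
    expect_equal(tabulate(cv$fold, k), as.vector(table(cv$fold)))
  }
  # shuffled labels give chance-level accuracy
  shuf <- sep
  set.seed(2)
  shuf$meta$class_label <- sample(shuf$meta$class_label)
  cvs <- kfold_cross_validate(shuf, regions, k = 4, seed = 3)
  expect_lt(abs(cvs$pooled_accuracy - 0.5), 3 * sqrt(0.25 / n_spectra(shuf)) + 0.05)

  # leave-one-out equals the explicit loop oracle on 12 spectra
  twelve <- subset_spectra(sep, c(1:6, 25:30))
  x <- extract_features(twelve, regions)
  lab <- twelve$meta$class_label
  loo <- kfold_cross_validate(twelve, regions, k = 12, seed = 5)
  oracle <- vapply(1:12, function(i) {
    m <- qda_fit(x[-i, , drop = FALSE], lab[-i], lambda = 1e-3)
    qda_predict(m, x[i, , drop = FALSE])
  }, character(1))
  expect_equal(mean(oracle == lab), loo$pooled_accuracy)
  expect_error(kfold_cross_validate(twelve, regions, k = 13, seed = 1),
               "exceeds")
})

test_that("sample classification averages posteriors and applies both rules", {
  train <- prep(planted_cohort(seed = 21, n_patients = 6, n_spectra = 4))
  regions <- preset_regions("normal_vs_tumor")
  model <- train_classifier(train, regions)
  res <- classify_samples(model, train)
  expect_s3_class(res, "sample_classification")
  expect_equal(nrow(res), length(unique(train$meta$sample_id)))
  post <- attr(res, "posteriors")
  # mean probability is the arithmetic mean of the per-spectrum posteriors
  key <- paste(train$meta$patient_id, train$meta$sample_id)
  i <- which(key == key[1])
  expect_equal(res$P_HCC[res$sample_id == train$meta$sample_id[1]][1],
               mean(post[i, "HCC"]), tolerance = 1e-12)
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  expect_true(all(res$assigned_class ==
                  ifelse(res$P_HCC > 0.5, "HCC", "normal") |
                  res$ambiguous))

  # preprocessing signature mismatch is refused
  raw <- planted_cohort(seed = 21, n_patients = 6, n_spectra = 4)
  expect_error(classify_samples(model, restrict_range(raw, 950, 1480)),
               "signature mismatch")
})

test_that("decision rules: binary p > 0.5, three-class argmax, flagged ties", {
  dec <- irtissue:::decide_class
  expect_equal(dec(c(normal = 0.2, tumor = 0.8), matrix(c(0.2, 0.8), 1),
                   c("normal", "tumor")),
               list(class = "tumor", ambiguous = FALSE))
  tie <- dec(c(normal = 0.5, tumor = 0.5), matrix(c(0.5, 0.5), 1),
             c("normal", "tumor"))
  expect_equal(tie$class, "tumor")   # conservative: ambiguous goes to tumor
  expect_true(tie$ambiguous)
  expect_equal(dec(c(0.2, 0.5, 0.3), matrix(c(0.2, 0.5, 0.3), 1),
                   c("metastasis", "CCC", "HCC"))$class, "CCC")
  mt <- dec(c(0.4, 0.4, 0.2),
            rbind(c(0.3, 0.6, 0.1), c(0.5, 0.2, 0.3)),
            c("metastasis", "CCC", "HCC"))
  expect_equal(mt$class, "CCC")      # highest single-spectrum posterior wins
  expect_true(mt$ambiguous)

  # three spectra with posteriors (0.9,0.1),(0.7,0.3),(0.8,0.2) -> mean (0.8,0.2)
  expect_equal(colMeans(rbind(c(0.9, 0.1), c(0.7, 0.3), c(0.8, 0.2))),
               c(0.8, 0.2))
})

test_that("probability grids report one row per sample with monotone colors", {
  train <- prep(planted_cohort(seed = 22, n_patients = 4, n_spectra = 3))
  model <- train_classifier(train, preset_regions("normal_vs_tumor"))
  res <- classify_samples(model, train)
  f <- tempfile(fileext = ".csv")
  grid <- render_probability_grid(res, path = f)
  expect_equal(nrow(grid$samples), nrow(res))
  expect_equal(nrow(utils::read.csv(f)), nrow(res))
  expect_equal(nrow(grid$cells), n_spectra(train))
  # color intensity monotone in posterior: higher p = farther from white
  pc <- irtissue:::probability_color
  dist_white <- function(p) sum(abs(grDevices::col2rgb(pc(p, "blue")) -
                                    c(255, 255, 255)))
  ps <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(ps, dist_white, numeric(1))) >= 0))
})
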