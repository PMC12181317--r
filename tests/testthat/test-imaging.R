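coarse_grid <- wavenumber_grid(950, 1800, by = 50)

# labelled tile whose every pixel stores its own (tile, row, col) code
coded_tile <- function(code, wn = c(950, 953)) {
  cube <- array(0, c(64, 64, length(wn)))
  for (r in 1:64) for (cc in 1:64) cube[r, cc, ] <- code * 1e6 + r * 100 + cc
  spectral_image(cube, wn)
}

test_that("mosaic assembly reproduces the 700 x 2100 um geometry", {
  tiles <- lapply(1:48, function(i)
    spectral_image(array(i, c(64, 64, 2)), c(950, 953)))
  mos <- assemble_mosaic(tiles, c(4, 12))
  expect_equal(dim(mos$cube)[1:2], c(256, 768))
  expect_equal(dim(mos$cube)[1] * mos$pixel_size_um, 700)
  expect_equal(dim(mos$cube)[2] * mos$pixel_size_um, 2100)
  one <- assemble_mosaic(tiles[1], c(1, 1))
  expect_equal(one$cube, tiles[[1]]$cube)
  expect_error(assemble_mosaic(tiles[1:3], c(2, 2)), "need 4 tiles")
})

test_that("tile pixels land at the row-major mosaic positions", {
  tiles <- lapply(1:6, coded_tile)
  mos <- assemble_mosaic(tiles, c(2, 3))
  set.seed(8)
  for (rep in 1:20) {
    i <- sample(2, 1); j <- sample(3, 1)
    r <- sample(64, 1); cc <- sample(64, 1)
    k <- (i - 1) * 3 + j     # row-major tile index
    expect_equal(mos$cube[64 * (i - 1) + r, 64 * (j - 1) + cc, 1],
                 k * 1e6 + r * 100 + cc)
  }
})

test_that("outlier filtering uses strict thresholds on sum and amide-I", {
  wn <- seq(1600, 1700, by = 10)   # 11 points, includes 1650
  mk_pixel <- function(total, amide) {
    v <- rep((total - amide) / 10, 11)
    v[wn == 1650] <- amide
    v
  }
  cube <- array(0, c(2, 2, 11))
  cube[1, 1, ] <- mk_pixel(19.9, 0.5)     # low sum -> masked
  cube[1, 2, ] <- mk_pixel(100, 0.009)    # low amide -> masked
  cube[2, 1, ] <- mk_pixel(20.0, 0.5)     # both at/above threshold -> kept
  cube[2, 2, ] <- mk_pixel(25, 0.01)      # amide exactly 0.01 -> kept
  img <- filter_image_outliers(spectral_image(cube, wn))
  expect_identical(img$outlier_mask,
                   matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  # raising the sum threshold never unmasks a pixel
  stricter <- filter_image_outliers(spectral_image(cube, wn),
                                    image_filter_spec(sum_threshold = 30))
  expect_true(all(img$outlier_mask <= stricter$outlier_mask))
  # no grid point near 1650 is an error
  expect_error(filter_image_outliers(spectral_image(cube[, , 1:3, drop = FALSE],
                                                    wn[1:3])), "within")
})

test_that("the filter recovers the simulated gap fraction", {
  m <- planted_band_models(noise_sd = 0.002)$normal
  img <- simulate_image(m, shape = c(1, 1), gap_fraction = 0.15,
                        grid = wavenumber_grid(950, 1800, by = 10), seed = 4)
  # the per-pixel sum scales with the grid: ~86 points of tissue signal
  filt <- filter_image_outliers(img, image_filter_spec(sum_threshold = 5))
  frac <- mean(filt$outlier_mask)
  expect_equal(frac, 0.15, tolerance = 0.02)
  none <- simulate_image(m, shape = c(1, 1), gap_fraction = 0,
                         grid = wavenumber_grid(950, 1800, by = 10), seed = 4)
  expect_equal(mean(filter_image_outliers(none,
               image_filter_spec(sum_threshold = 5))$outlier_mask), 0,
               tolerance = 0.001)
})

test_that("contrast images sum the closed window and blank masked pixels", {
  wn <- seq(950, 1000, by = 10)
  cube <- array(0.5, c(2, 3, 6))
  img <- spectral_image(cube, wn)
  expect_true(all(contrast_image(img, 950, 1000) == 3))
  img$outlier_mask[1, 2] <- TRUE
  cm <- contrast_image(img, 950, 1000)
  expect_true(is.na(cm[1, 2]))
  expect_error(contrast_image(img, 1200, 1300), "no grid points")
  # random cube against an explicit per-pixel loop
  set.seed(9)
  rc <- array(stats::rnorm(2 * 3 * 6), c(2, 3, 6))
  ri <- spectral_image(rc, wn)
  got <- contrast_image(ri, 960, 990)
  idx <- window_indices(wn, 960, 990)
  for (r in 1:2) for (cc in 1:3)
    expect_equal(got[r, cc], sum(rc[r, cc, idx]))
})

test_that("mean spectra use the sample standard deviation", {
  wn <- c(950, 952, 954)
  s <- tiny_set(rbind(c(1, 2, 3), c(1, 2, 3)), wn)
  ms <- mean_spectrum(s, area_normalize_first = FALSE)
  expect_equal(ms$mean, c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(ms$sd, c(0, 0, 0), ignore_attr = TRUE)
  s2 <- tiny_set(rbind(c(0, 1, 1), c(2, 1, 1)), wn)
  ms2 <- mean_spectrum(s2, area_normalize_first = FALSE)
  expect_equal(ms2$mean[1], 1, ignore_attr = TRUE)
  expect_equal(ms2$sd[1], sqrt(2), ignore_attr = TRUE)  # sample sd of {0, 2}
  # area-normalized mean sums to 1 over the normalization range
  set.seed(10)
  s3 <- tiny_set(matrix(stats::runif(15, 0.1, 1), 5), wn)
  ms3 <- mean_spectrum(s3, norm_range = c(950, 954))
  expect_equal(sum(ms3$mean), 1, tolerance = 1e-12)
  # works straight off image pixels
  img <- spectral_image(array(stats::runif(2 * 2 * 3, 0.1, 1), c(2, 2, 3)), wn)
  img$outlier_mask[1, 1] <- TRUE
  mi <- mean_spectrum(img, area_normalize_first = FALSE)
  expect_equal(mi$n, 3)
})
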