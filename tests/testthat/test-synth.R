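test_that("speckle patterns hit the requested statistics, deterministically", {
  spec <- pattern_spec(c(256, 256), speckle_size = 4, visibility = 0.3,
                       mean_counts = 1e4, seed = 31)
  img <- generate_speckle_pattern(spec)
  expect_identical(img, generate_speckle_pattern(spec))  # same seed
  expect_true(all(img >= 0))
  expect_lt(abs(mean(img) / 1e4 - 1), 0.02)
  expect_lt(abs(stats::sd(img) / mean(img) / 0.3 - 1), 0.1)
  fwhm <- oracle_acf_fwhm(img)
  expect_gt(fwhm, 3.2)
  expect_lt(fwhm, 4.8)

  img2 <- generate_speckle_pattern(pattern_spec(c(256, 256), seed = 32))
  expect_false(identical(img, img2))
  expect_lt(abs(stats::sd(img2) / mean(img2) - 0.3), 0.03)
})

test_that("spiral positions: spacing and distinct components", {
  expect_equal(spiral_positions(1, 5), cbind(x = 0, y = 0))
  p <- spiral_positions(2, 3)
  expect_true(all(abs(p[2, ]) > 1e-9))       # differs in both coordinates
  p <- spiral_positions(25, 8)
  expect_gte(min(stats::dist(p)), 8)
  expect_identical(anyDuplicated(p[, 1]), 0L)
  expect_identical(anyDuplicated(p[, 2]), 0L)
})

test_that("synthesize_dataset degenerate phantoms", {
  H <- 48
  labels <- matrix(1L, H, H)
  id <- data.frame(label = 1, T = 1, ux = 0, uy = 0, sigma_major = 0.01,
                   sigma_minor = 0.01, theta = 0)
  ds <- synthesize_dataset(pattern_spec(c(H, H), seed = 33),
                           phantom_spec(labels, id),
                           acquisition_spec(n_positions = 3, noise = FALSE))
  expect_equal(ds$frames$sample, ds$frames$reference, tolerance = 1e-12)

  half <- transform(id, T = 0.5)
  ds <- synthesize_dataset(pattern_spec(c(H, H), seed = 33),
                           phantom_spec(labels, half),
                           acquisition_spec(n_positions = 3, noise = FALSE))
  expect_equal(ds$frames$sample, 0.5 * ds$frames$reference,
               tolerance = 1e-12)

  # ground truth is co-registered and shape-consistent
  expect_identical(dim(ds$truth$T), dim(labels))
  expect_identical(dim(ds$frames$sample)[1:2], dim(labels))
  expect_true(all(ds$truth$T == 0.5))

  expect_error(
    synthesize_dataset(matrix(1, 50, 50), phantom_spec(labels, id),
                       acquisition_spec(n_positions = 25)),
    "too small")
})

test_that("Poisson noise and reference averaging behave statistically", {
  H <- 100
  labels <- matrix(1L, H, H)
  id <- data.frame(label = 1, T = 1, ux = 0, uy = 0, sigma_major = 0.01,
                   sigma_minor = 0.01, theta = 0)
  mu <- 1e4
  ds <- synthesize_dataset(
    pattern_spec(c(H, H), mean_counts = mu, visibility = 0.3, seed = 34),
    phantom_spec(labels, id),
    acquisition_spec(n_positions = 8, n_reference_averages = 16,
                     noise = TRUE, seed = 35))
  dsc <- synthesize_dataset(
    pattern_spec(c(H, H), mean_counts = mu, visibility = 0.3, seed = 34),
    phantom_spec(labels, id),
    acquisition_spec(n_positions = 8, n_reference_averages = 16,
                     noise = FALSE))
  # per-pixel variance of repeated sample frames ~ clean intensity
  dev <- ds$frames$sample - dsc$frames$sample
  v <- apply(dev, c(1, 2), stats::var)
  expect_lt(abs(mean(v) / mean(dsc$frames$sample) - 1), 0.1)
  # reference averaging divides the noise variance by the average count
  vr <- apply(ds$frames$reference - dsc$frames$reference, c(1, 2),
              stats::var)
  expect_lt(abs(sqrt(mean(vr) * 16 / mean(v)) - 1), 0.15)
})

test_that("four-tube phantom geometry and warning contracts", {
  ph <- four_tube_phantom(c(64, 64))
  expect_setequal(unique(as.vector(ph$labels)), 1:4)
  expect_equal(ph$regions$theta,
               speckleddf:::wrap_axial(ph$regions$fibre_angle + 90))
  expect_warning(
    synthesize_dataset(pattern_spec(c(48, 48), speckle_size = 3, seed = 1),
                       phantom_spec(matrix(1L, 48, 48),
                                    data.frame(label = 1, T = 1, ux = 0,
                                               uy = 0, sigma_major = 0.01,
                                               sigma_minor = 0.01,
                                               theta = 0)),
                       acquisition_spec(n_positions = 3, step = 2,
                                        noise = FALSE)),
    "speckle size")
  expect_error(acquisition_spec(n_positions = 0), "n_positions")
})
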