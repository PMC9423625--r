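test_that("kernel parameter validation names the violated inequality", {
  expect_error(blur_kernel(-1, 0, 1), "alpha1 > 0")
  expect_error(blur_kernel(1, 0, 0), "alpha3 > 0")
  expect_error(blur_kernel(1, 1.1, 1), "alpha1\\*alpha3 - alpha2\\^2")
  expect_s3_class(blur_kernel(1, 0.99, 1), "ddf_kernel_params")
})

test_that("rasterised kernels are normalised, symmetric and isotropic when due", {
  k <- evaluate_kernel(blur_kernel(1, 0, 1), support_radius = 5)$weights
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(k, t(k), tolerance = 1e-14)            # x/y exchange symmetry
  for (p in list(c(1, 0, 1), c(2, 1, 2), c(4, -1.5, 1), c(0.3, 0.2, 0.8))) {
    w <- evaluate_kernel(blur_kernel(p[1], p[2], p[3]))$weights
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # point symmetry: w(x, y) == w(-x, -y)
    expect_equal(w, w[rev(seq_len(nrow(w))), rev(seq_len(ncol(w)))],
                 tolerance = 1e-14)
  }
  expect_error(evaluate_kernel(blur_kernel(1, 0, 1), support_radius = 0),
               ">= 1")
})

test_that("discrete kernel moments match dense integration of the model", {
  k <- evaluate_kernel(blur_kernel(2, 1, 2), support_radius = 6)$weights
  got <- raster_moments(k)$cov
  want <- oracle_continuous_cov(2, 1, 2)
  expect_equal(want[1, 1], 2 / 3, tolerance = 1e-4)  # oracle sanity
  expect_lt(max(abs(got - want)) / max(abs(want)), 0.01)
  expect_equal(got[1, 1], 2 / 3, tolerance = 0.01)
  expect_equal(got[1, 2], -1 / 3, tolerance = 0.01)
})

test_that("alpha_to_axes matches the eigen-decomposition oracle", {
  ax <- alpha_to_axes(blur_kernel(1, 0, 1))
  expect_equal(ax$sigma_major, 1)
  expect_equal(ax$sigma_minor, 1)
  expect_identical(ax$theta, 0)
  expect_true(ax$isotropic)

  ax <- alpha_to_axes(blur_kernel(4, 0, 1))
  expect_equal(ax$sigma_major, 1, tolerance = 1e-12)
  expect_equal(ax$sigma_minor, 0.5, tolerance = 1e-12)
  expect_equal(ax$theta, 90)

  ax <- alpha_to_axes(blur_kernel(2, 1, 2))
  expect_equal(ax$sigma_major, 1, tolerance = 1e-12)
  expect_equal(ax$sigma_minor, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(ax$theta, -45)

  # against eigen() and against the rasterised-kernel moment orientation
  set.seed(5)
  for (i in 1:25) {
    a <- axes_to_alpha(runif(1, 1, 3), runif(1, 0.5, 0.9), runif(1, -89, 90))
    M <- matrix(c(a$alpha1, a$alpha2, a$alpha2, a$alpha3), 2)
    ev <- eigen(M, symmetric = TRUE)
    ax <- alpha_to_axes(a)
    expect_equal(ax$sigma_major, 1 / sqrt(min(ev$values)), tolerance = 1e-10)
    expect_equal(ax$sigma_minor, 1 / sqrt(max(ev$values)), tolerance = 1e-10)
  }
})

test_that("axes_to_alpha inverts alpha_to_axes (property, 1000 cases)", {
  a <- axes_to_alpha(1, 1, 33)
  expect_equal(c(a$alpha1, a$alpha2, a$alpha3), c(1, 0, 1),
               tolerance = 1e-12)
  a <- axes_to_alpha(1, 0.5, 90)
  expect_equal(c(a$alpha1, a$alpha2, a$alpha3), c(4, 0, 1),
               tolerance = 1e-12)
  expect_error(axes_to_alpha(0.5, 1, 0), "sigma_major")
  expect_error(axes_to_alpha(1, -0.1, 0), "positive")

  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    sM <- runif(1, 0.1, 5)
    sm <- sM * runif(1, 0.02, 0.999)
    th <- runif(1, -89.999, 90)
    ax <- alpha_to_axes(axes_to_alpha(sM, sm, th))
    dth <- abs(ax$theta - th)
    dth <- min(dth, 180 - dth) * pi / 180 * sM  # scale angle into length units
    worst <- max(worst, abs(ax$sigma_major - sM) / sM,
                 abs(ax$sigma_minor - sm) / sm, dth / sM)
  }
  expect_lt(worst, 1e-9)
})

test_that("model_intensity: identity limit, conservation, integer roll", {
  set.seed(2)
  img <- matrix(runif(24 * 30, 1, 2), 24, 30)
  delta <- blur_kernel(1e4, 0, 1e4)  # widths 0.01 << 0.05 floor

  expect_lt(max(abs(model_intensity(img, 1, c(0, 0), delta) - img)), 1e-6)

  out <- model_intensity(matrix(2, 20, 20), 0.5, c(0, 0), blur_kernel(1, 0, 1))
  expect_equal(out, matrix(1, 20, 20), tolerance = 1e-12)

  out <- model_intensity(img, 1, c(3, 0), delta)
  inner_r <- 5:20; inner_c <- 5:24
  expect_equal(out[inner_r, inner_c], img[inner_r, inner_c + 3],
               tolerance = 1e-12)

  expect_error(model_intensity(img, 1, c(50, 0), delta), "exceeds")
})

test_that("unit-sum kernels conserve the interior mean for any valid alpha", {
  set.seed(8)
  img <- matrix(runif(60 * 60, 1, 3), 60, 60)
  for (p in list(c(1, 0, 1), c(0.25, 0.1, 0.5), c(2, -1, 2))) {
    out <- model_intensity(img, 1, c(0, 0), blur_kernel(p[1], p[2], p[3]))
    inner <- 15:46
    expect_equal(mean(out[inner, inner]), mean(img[inner, inner]),
                 tolerance = 1e-3)
  }
})

test_that("blurring monotonically reduces speckle visibility", {
  set.seed(9)
  img <- matrix(runif(80 * 80, 1, 3), 80, 80)
  inner <- 20:60
  vis <- sapply(c(0.3, 0.6, 1, 1.6, 2.5), function(s) {
    out <- model_intensity(img, 1, c(0, 0), axes_to_alpha(1.4 * s, 0.7 * s, 20))
    v <- out[inner, inner]
    stats::sd(v) / mean(v)
  })
  expect_true(all(diff(vis) < 0))
})

test_that("axes orientation agrees with rasterised-kernel moments to 0.5 deg", {
  set.seed(10)
  for (i in 1:20) {
    sM <- runif(1, 1.0, 3)
    sm <- sM * runif(1, 0.3, 0.65)   # eccentricity > 0.2, widths >= 0.8
    sm <- max(sm, 0.8)
    th <- runif(1, -89, 90)
    a <- axes_to_alpha(sM, sm, th)
    K <- evaluate_kernel(a)$weights
    dth <- abs(raster_moments(K)$theta - alpha_to_axes(a)$theta)
    expect_lt(min(dth, 180 - dth), 0.5)
  }
})

test_that("speckle_frame_set enforces shape and positivity contracts", {
  s <- array(1, dim = c(8, 8, 2))
  expect_error(speckle_frame_set(s, array(1, dim = c(8, 8, 3))), "identical")
  bad <- s; bad[1, 1, 1] <- -1
  expect_error(speckle_frame_set(bad, s), "non-negative")
  bad[1, 1, 1] <- NA
  expect_error(speckle_frame_set(bad, s), "finite")
  fr <- speckle_frame_set(s, s)
  expect_identical(fr$n_positions, 2L)
})
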