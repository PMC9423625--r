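test_that("darkfield_summary worked values", {
  d <- darkfield_summary(blur_kernel(1, 0, 1))
  expect_equal(d$sigma, 1)
  expect_equal(d$eccentricity, 0)
  expect_true(d$isotropic)
  expect_identical(d$theta, 0)

  # sigma^2 = 0.625, ecc = 0.6, theta = 90 (verified against the
  # rasterised-kernel moment oracle below)
  d <- darkfield_summary(blur_kernel(4, 0, 1))
  expect_equal(d$sigma^2, 0.625, tolerance = 1e-12)
  expect_equal(d$eccentricity, 0.6, tolerance = 1e-12)
  expect_equal(d$theta, 90)
  K <- evaluate_kernel(blur_kernel(4, 0, 1))$weights
  mom <- raster_moments(K)
  expect_equal(sum(diag(mom$cov)) / 2, 0.625, tolerance = 0.01)
  expect_equal(abs(mom$theta), 90, tolerance = 0.5)

  # directionality equals the width form (sigmaM^2 - sigmam^2)/(sum):
  # (1 - 1/3) / (1 + 1/3) = 0.5 for alpha = (2, 1, 2)
  d <- darkfield_summary(blur_kernel(2, 1, 2))
  expect_equal(d$sigma, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(d$eccentricity, 0.5, tolerance = 1e-12)
  expect_equal(d$theta, -45)
  ax <- alpha_to_axes(blur_kernel(2, 1, 2))
  expect_equal(d$eccentricity,
               (ax$sigma_major^2 - ax$sigma_minor^2) /
                 (ax$sigma_major^2 + ax$sigma_minor^2), tolerance = 1e-12)
})

test_that("summary formulas agree with the eigen route over 1000 kernels", {
  set.seed(21)
  for (i in 1:1000) {
    sM <- runif(1, 0.1, 4)
    sm <- sM * runif(1, 0.05, 1)
    th <- runif(1, -90, 90)
    p <- axes_to_alpha(sM, max(sm, 1e-3), th)
    d <- darkfield_summary(p)
    ax <- alpha_to_axes(p)
    expect_equal(d$sigma, sqrt((ax$sigma_major^2 + ax$sigma_minor^2) / 2),
                 tolerance = 1e-10)
    expect_equal(d$eccentricity,
                 (ax$sigma_major^2 - ax$sigma_minor^2) /
                   (ax$sigma_major^2 + ax$sigma_minor^2), tolerance = 1e-10)
    if (!d$isotropic) {
      dth <- abs(d$theta - ax$theta)
      expect_lt(min(dth, 180 - dth), 1e-8)
    }
    expect_true(d$eccentricity >= 0 && d$eccentricity < 1)
  }
})

test_that("refraction maps follow u * pixel_size / d in microradians", {
  g <- geometry_spec(21.5e-6, 6.65)
  maps <- list(ux = matrix(c(0, 1, -2, 0.5), 2), uy = matrix(0, 2, 2))
  rm <- refraction_maps(maps, g)
  expect_equal(rm$angle_y, matrix(0, 2, 2))
  expect_equal(rm$angle_x[2, 1], 21.5e-6 / 6.65 * 1e6, tolerance = 1e-12)
  expect_equal(rm$angle_x[2, 1], 3.233, tolerance = 1e-3)
  g2 <- geometry_spec(21.5e-6, 2 * 6.65)
  expect_equal(refraction_maps(maps, g2)$angle_x, rm$angle_x / 2)
})

test_that("hsv composite semantics: grey, black, axial hue continuity", {
  th <- matrix(c(0, 45, 89.9, -89.9), 2)
  ec <- matrix(c(0, 0.8, 0.8, 0.8), 2)
  sg <- matrix(c(1, 1, 1, 0), 2)
  rgb <- hsv_composite(th, ec, sg, value_clip = 1)
  # ecc = 0 pixel is grey: equal channels
  expect_equal(rgb[1, 1, 1], rgb[1, 1, 2])
  expect_equal(rgb[1, 1, 2], rgb[1, 1, 3])
  # sigma = 0 pixel is black whatever the angle
  expect_equal(as.vector(rgb[2, 2, ]), c(0, 0, 0))
  # hue distance across the axial wrap is smaller than 0 vs 45 deg
  hue_dist <- function(a, b) {
    d <- abs(a - b); min(d, 1 - d)
  }
  hue_of <- function(theta) (theta + 90) / 180
  expect_lt(hue_dist(hue_of(89.9), hue_of(-89.9)),
            hue_dist(hue_of(0), hue_of(45)))
  d1 <- sqrt(sum((rgb[1, 2, ] - rgb[2, 1, ])^2))  # 89.9 vs -89.9 colours
  rgb2 <- hsv_composite(matrix(c(0, 45), 1), matrix(c(0.8, 0.8), 1),
                        matrix(c(1, 1), 1), value_clip = 1)
  d2 <- sqrt(sum((rgb2[1, 1, ] - rgb2[1, 2, ])^2))
  expect_lt(d1, d2)
})

test_that("orientation maps rotate with the phantom (rotation equivariance)", {
  for (phi in c(30, 45, 90)) {
    ds <- uniform_phantom_ds(80, noise = FALSE, axes = c(2, 1, -20),
                             seed = 3, n_positions = 9)
    dsr <- uniform_phantom_ds(80, noise = FALSE,
                              axes = c(2, 1, speckleddf:::wrap_axial(-20 + phi)),
                              seed = 3, n_positions = 9)
    cfg <- solver_config(window = 7, levels = 1, max_shift = 3, step = 11)
    m0 <- solve_level(ds$frames, cfg)
    mr <- solve_level(dsr$frames, cfg)
    t0 <- darkfield_summary(m0)$theta[m0$mask]
    tr <- darkfield_summary(mr)$theta[mr$mask]
    d <- speckleddf:::wrap_axial(tr - t0 - phi)
    expect_lt(mean(abs(d)), 2)
  }
})
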