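test_that("hamming window and config contracts", {
  w <- hamming_window(7)
  expect_identical(dim(w$weights), c(7L, 7L))
  expect_equal(max(w$weights), 1)
  expect_gt(w$weights[4, 4], 0)
  expect_error(hamming_window(4), "odd")
  expect_error(solver_config(levels = c(2, 4, 1)), "decreasing")
  expect_error(solver_config(levels = c(4, 2)), "last level")
})

test_that("cost_function: perfect model and closed forms", {
  set.seed(11)
  H <- 11L
  ref <- array(runif(H * H * 2, 0.5, 2), dim = c(H, H, 2))
  fr <- speckle_frame_set(ref, ref)
  delta <- blur_kernel(1e4, 0, 1e4)
  expect_equal(as.numeric(
    cost_function(fr, c(6, 6), 1, c(0, 0), delta, window = 3)), 0,
    tolerance = 1e-20)

  # T = 0: cost reduces to the Gamma-weighted sum of squared intensities
  fr2 <- cost_fixture()
  G <- hamming_window(3)$weights
  want <- 0
  for (j in 1:2) for (ty in -1:1) for (tx in -1:1)
    want <- want + G[ty + 2, tx + 2] * fr2$sample[6 + ty, 6 + tx, j]^2
  got <- cost_function(fr2, c(6, 6), 0, c(0, 0), delta, window = 3)
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
})

test_that("cost_function matches the straight-loop oracle to 1e-10", {
  fr <- cost_fixture()
  G <- hamming_window(3)$weights
  set.seed(12)
  for (i in 1:6) {
    Tval <- runif(1, 0.3, 1.5)
    u <- runif(2, -0.9, 0.9)
    a <- axes_to_alpha(runif(1, 0.2, 0.35), runif(1, 0.1, 0.2),
                       runif(1, -90, 90))
    K <- evaluate_kernel(a)$weights
    want <- oracle_cost(fr$sample, fr$reference, c(6, 6), Tval, u, K, G)
    got <- cost_function(fr, c(6, 6), Tval, u, a, window = 3)
    expect_equal(as.numeric(got), want, tolerance = 1e-10)
  }
  expect_error(cost_function(fr, c(2, 2), 1, c(0, 0),
                             blur_kernel(1, 0, 1), window = 3), "margin")
})

test_that("optimal_transmission: proportionality, noise, scalar oracle", {
  set.seed(13)
  H <- 11L
  ref <- array(runif(H * H * 2, 0.5, 2), dim = c(H, H, 2))
  delta <- blur_kernel(1e4, 0, 1e4)

  fr <- speckle_frame_set(0.37 * ref, ref)
  expect_equal(optimal_transmission(fr, c(6, 6), c(0, 0), delta, window = 3),
               0.37, tolerance = 1e-12)

  # uncorrelated noise: T* near 0 (|T*| < 3/sqrt(P))
  nz <- array(pmax(matrix(rnorm(H * H * 2), H), 0), dim = c(H, H, 2))
  frn <- speckle_frame_set(nz, ref)
  P <- 9 * 2
  expect_lt(abs(optimal_transmission(frn, c(6, 6), c(0, 0), delta,
                                     window = 3)), 3 / sqrt(P))

  # matches 1-D minimisation of the cost over T
  fr2 <- cost_fixture()
  a <- axes_to_alpha(0.3, 0.2, 40)
  u <- c(0.4, -0.3)
  Topt <- optimal_transmission(fr2, c(6, 6), u, a, window = 3)
  Tgold <- stats::optimize(function(Tv) as.numeric(
    cost_function(fr2, c(6, 6), Tv, u, a, window = 3)),
    interval = c(-2, 4), tol = 1e-12)$minimum
  expect_equal(Topt, Tgold, tolerance = 1e-8)
  c0 <- cost_function(fr2, c(6, 6), Topt, u, a, window = 3)
  for (Tv in Topt + c(-0.05, 0.05))
    expect_gt(as.numeric(cost_function(fr2, c(6, 6), Tv, u, a, window = 3)),
              as.numeric(c0))
})

test_that("solve_pixel recovers a known noiseless pixel", {
  ds <- fixture("uniform96", function() uniform_phantom_ds(96, noise = FALSE))
  cfg <- solver_config(window = 7, levels = 1, max_shift = 3)
  sol <- solve_pixel(ds$frames, c(48, 48), config = cfg)
  ax <- alpha_to_axes(sol$params)
  expect_lt(abs(sol$transmittance - 0.8), 0.01)
  expect_lt(max(abs(sol$u - c(0.6, -0.4))), 0.05)
  expect_lt(abs(ax$theta - 30), 2)

  # fixed point: starting at the optimum leaves the solution unchanged
  sol2 <- solve_pixel(ds$frames, c(48, 48), config = cfg,
                      init = list(u = sol$u, params = sol$params))
  expect_lt(max(abs(sol2$u - sol$u)), 0.01)
  expect_lt(abs(sol2$transmittance - sol$transmittance), 0.005)
  expect_lte(sol2$residual, sol$residual * (1 + 1e-6) + 1e-12)
})

test_that("solver cost is at least as good as dense grid search (oracle)", {
  # tiny problem: 13 x 13, N = 2, 3 x 3 window, sub-pixel kernel; counting
  # noise keeps the cost floor finite so the comparison is well-posed
  set.seed(14)
  H <- 13L
  ref <- array(runif(H * H * 2, 1, 2), dim = c(H, H, 2))
  truth <- list(T = 0.9, u = c(0.3, -0.2), a = axes_to_alpha(0.3, 0.22, 20))
  sam <- array(0, dim = dim(ref))
  for (j in 1:2)
    sam[, , j] <- model_intensity(ref[, , j], truth$T, truth$u, truth$a)
  sam <- sam * (1 + array(rnorm(length(sam), sd = 0.01), dim = dim(sam)))
  fr <- speckle_frame_set(sam, ref)
  cfg <- solver_config(window = 3, levels = 1, max_shift = 1,
                       width_bounds = c(0.02, 0.45), grid_widths = c(0, 0.3),
                       param_tol = 1e-6, cost_tol = 1e-10, max_eval = 2000)
  sol <- solve_pixel(fr, c(7, 7), config = cfg)

  best <- Inf
  for (ux in truth$u[1] + seq(-0.1, 0.1, by = 0.05))
    for (uy in truth$u[2] + seq(-0.1, 0.1, by = 0.05))
      for (sM in truth_sM <- 0.3 * c(0.9, 1, 1.1))
        for (sm in 0.22 * c(0.9, 1, 1.1))
          for (th in 20 + c(-10, 0, 10)) {
            a <- axes_to_alpha(max(sM, sm), min(sM, sm), th)
            cc <- cost_function(fr, c(7, 7), NA, c(ux, uy), a, window = 3)
            best <- min(best, as.numeric(cc))
          }
  expect_lte(sol$residual, best * (1 + 1e-6))
})

test_that("solve_level: uniform agreement, determinism, independence", {
  ds <- fixture("uniform96", function() uniform_phantom_ds(96, noise = FALSE))
  cfg <- solver_config(window = 7, levels = 1, max_shift = 3, step = 7)
  m1 <- solve_level(ds$frames, cfg)
  expect_true(any(m1$mask))
  # translation invariance: all interior pixels agree within tolerance
  df <- darkfield_summary(m1)
  expect_lt(max(df$theta[m1$mask]) - min(df$theta[m1$mask]), 0.5)
  expect_lt(max(m1$T[m1$mask]) - min(m1$T[m1$mask]), 0.005)
  # determinism: bit-identical re-run
  m2 <- solve_level(ds$frames, cfg)
  expect_identical(m1$T, m2$T)
  expect_identical(m1$a2, m2$a2)
  expect_error(
    solve_level(speckle_frame_set(ds$frames$sample[1:20, 1:20, , drop = FALSE],
                                  ds$frames$reference[1:20, 1:20, , drop = FALSE]),
                cfg), "margin|larger")
})

test_that("multires: degenerate cascade, binning consistency, cascade help", {
  ds <- fixture("uniform96_2px", function()
    uniform_phantom_ds(96, noise = FALSE, u = c(2, 1)))
  cfg1 <- solver_config(window = 7, levels = 1, max_shift = 3, step = 6)
  expect_identical(multires_solve(ds$frames, cfg1)$T,
                   solve_level(ds$frames, cfg1)$T)

  # binned solve sees half the shift; the cascade rescales it back
  fb <- speckleddf:::bin_frames(ds$frames, 2L)
  cfgb <- solver_config(window = 5, levels = 1, max_shift = 2, step = 4,
                        width_bounds = c(0.02, 1.6))
  mb <- solve_level(fb, cfgb)
  expect_equal(mean(mb$ux[mb$mask]), 1, tolerance = 0.05)
  expect_equal(mean(mb$uy[mb$mask]), 0.5, tolerance = 0.05)

  cfg <- solver_config(window = 7, levels = c(4, 2, 1), max_shift = 3,
                       step = 6)
  mm <- multires_solve(ds$frames, cfg)
  expect_equal(mean(mm$ux[mm$mask]), 2, tolerance = 0.05)
  expect_equal(mean(mm$uy[mm$mask]), 1, tolerance = 0.05)

  # the cascade is not worse than the single-level solve on the fixture
  df1 <- darkfield_summary(multires_solve(ds$frames, cfg1))
  dfm <- darkfield_summary(mm)
  m1 <- multires_solve(ds$frames, cfg1)
  e1 <- mean(abs(df1$theta[m1$mask] - 30))
  em <- mean(abs(dfm$theta[mm$mask] - 30))
  expect_lte(em, e1 + 0.1)
})

test_that("shift equivariance and intensity scaling", {
  ds <- fixture("uniform96", function() uniform_phantom_ds(96, noise = FALSE))
  cfg <- solver_config(window = 7, levels = 1, max_shift = 3)
  r0 <- c(48, 48)
  base <- solve_pixel(ds$frames, r0, config = cfg)

  # translate all sample frames by v = (1, 1): I'(r) = I(r + v)
  H <- dim(ds$frames$sample)[1]
  shifted <- ds$frames$sample[c(2:H, H), c(2:H, H), , drop = FALSE]
  frs <- speckle_frame_set(shifted, ds$frames$reference)
  sol <- solve_pixel(frs, r0, config = cfg)
  expect_lt(max(abs(sol$u - (base$u + c(1, 1)))), 0.05)

  frc <- speckle_frame_set(1.7 * ds$frames$sample, ds$frames$reference)
  solc <- solve_pixel(frc, r0, config = cfg)
  expect_lt(abs(solc$transmittance / base$transmittance - 1.7) / 1.7, 0.005)
})

test_that("degenerate window: vanishing model term is an error", {
  H <- 11L
  zero <- array(0, dim = c(H, H, 2))
  ones <- array(1, dim = c(H, H, 2))
  fr <- speckle_frame_set(ones, zero)
  expect_error(optimal_transmission(fr, c(6, 6), c(0, 0),
                                    blur_kernel(1e4, 0, 1e4), window = 3),
               "degenerate")
})

test_that("non-finite data is rejected", {
  ds <- fixture("uniform96", function() uniform_phantom_ds(96, noise = FALSE))
  bad <- ds$frames
  expect_error(speckle_frame_set(ds$frames$sample * NA, ds$frames$reference),
               "finite")
})
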