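# Independent oracles: deliberately naive straight-loop implementations used
# to pin down the fast paths.  They share only mathematical definitions with
# the package internals, not code.

# Catmull-Rom interpolation of img (matrix) at 0-based coordinates (x, y)
oracle_interp <- function(img, x, y) {
  cw <- function(f) c(0.5 * (-f^3 + 2 * f^2 - f),
                      0.5 * (3 * f^3 - 5 * f^2 + 2),
                      0.5 * (-3 * f^3 + 4 * f^2 + f),
                      0.5 * (f^3 - f^2))
  xb <- floor(x); yb <- floor(y)
  wx <- cw(x - xb); wy <- cw(y - yb)
  v <- 0
  # 0-based support rows yb-1 .. yb+2 are R indices yb .. yb+3
  for (ky in 0:3) for (kx in 0:3)
    v <- v + wy[ky + 1] * wx[kx + 1] * img[yb + ky, xb + kx]
  v
}

# windowed least-squares cost, literal double sum (Eq-2 style)
oracle_cost <- function(sample, reference, r0, Tval, u, K, G) {
  wh <- (nrow(G) - 1) / 2
  R <- (nrow(K) - 1) / 2
  x0 <- r0[2] - 1; y0 <- r0[1] - 1   # 0-based centre
  total <- 0
  for (j in seq_len(dim(sample)[3])) {
    ref <- reference[, , j]
    for (ty in -wh:wh) for (tx in -wh:wh) {
      I <- sample[r0[1] + ty, r0[2] + tx, j]
      M <- 0
      for (ky in -R:R) for (kx in -R:R)
        M <- M + K[ky + R + 1, kx + R + 1] *
          oracle_interp(ref, x0 + tx + u[1] - kx, y0 + ty + u[2] - ky)
      total <- total + G[ty + wh + 1, tx + wh + 1] * (I - Tval * M)^2
    }
  }
  total
}

# continuous second moments of the kernel by dense numerical integration
oracle_continuous_cov <- function(a1, a2, a3, half = 10, h = 0.05) {
  g <- seq(-half, half, by = h)
  xx <- outer(rep(1, length(g)), g)
  yy <- outer(g, rep(1, length(g)))
  w <- exp(-0.5 * (a1 * xx^2 + 2 * a2 * xx * yy + a3 * yy^2))
  w <- w / sum(w)
  matrix(c(sum(w * xx^2), sum(w * xx * yy), sum(w * xx * yy),
           sum(w * yy^2)), 2)
}

# discrete second moments and major-axis orientation of a kernel raster
raster_moments <- function(K) {
  R <- (nrow(K) - 1) / 2
  g <- -R:R
  xx <- outer(rep(1, nrow(K)), g)
  yy <- outer(g, rep(1, nrow(K)))
  C <- matrix(c(sum(K * xx^2), sum(K * xx * yy), sum(K * xx * yy),
                sum(K * yy^2)), 2)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  list(cov = C, theta = speckleddf:::wrap_axial(atan2(v[2], v[1]) * 180 / pi))
}

# autocorrelation FWHM of an image via FFT (average of x and y cuts)
oracle_acf_fwhm <- function(img) {
  z <- img - mean(img)
  ac <- Re(stats::fft(Mod(stats::fft(z))^2, inverse = TRUE))
  ac <- ac / ac[1, 1]
  fwhm_1d <- function(v) {
    # v[1] is lag 0; first crossing of 0.5, linear interpolation
    i <- which(v < 0.5)[1]
    if (is.na(i)) return(NA_real_)
    lo <- i - 2; hi <- i - 1  # lags
    2 * (lo + (v[i - 1] - 0.5) / (v[i - 1] - v[i]))
  }
  mean(c(fwhm_1d(ac[1, ]), fwhm_1d(ac[, 1])))
}
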