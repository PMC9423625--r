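# Axial (mod-180) circular statistics and orientation-map evaluation.

#' Axial mean and standard deviation
#'
#' Orientations are defined modulo 180 degrees, so ordinary statistics are
#' meaningless near the wrap.  The double-angle method doubles the angles,
#' takes the circular mean and circular standard deviation, and halves the
#' results; the mean is reported in `(-90, 90]`.
#'
#' @param angles numeric vector of angles in degrees (any representatives of
#'   the axial classes).
#' @return Named numeric vector `c(mean, sd)` in degrees.
#' @examples
#' axial_mean_sd(c(89, -89, 88))  # mean near the wrap, small sd
#' @export
axial_mean_sd <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) stop("empty axial sample")
  a <- angles * pi / 90  # doubled angle in radians
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  m <- wrap_axial(atan2(S, C) / 2 * 180 / pi)
  s <- if (R <= 0) Inf else sqrt(-2 * log(min(R, 1))) / 2 * 180 / pi
  c(mean = m, sd = s)
}

#' Number of independent pixel measurements
#'
#' `P = window_size^2 * n_positions`: the number of pixels in the analysis
#' window times the number of diffuser positions.  `P` governs the precision
#' of the retrieved orientation.
#'
#' @param window_size analysis window side, pixels.
#' @param n_positions number of diffuser positions.
#' @return Integer-valued count `P`.
#' @examples
#' independent_measurements(31, 25)  # 24025
#' @export
independent_measurements <- function(window_size, n_positions) {
  stopifnot(window_size >= 1, n_positions >= 1)
  as.numeric(window_size)^2 * n_positions
}

#' Precision-scaling power-law fit
#'
#' Fits `sigma_theta = A * P^B` by linear regression of `log(sigma_theta)`
#' on `log(P)`, weighted by the supplied standard errors when given.  Points
#' with `P` below the exclusion threshold are dropped (their standard
#' deviations are meaningless once the orientation histogram wraps around).
#'
#' @param P numbers of independent measurements.
#' @param sigma_theta orientation standard deviations (degrees).
#' @param se optional standard errors of `sigma_theta`.
#' @param exclude_below exclusion threshold on `P` (default 50).
#' @return Object of class `ddf_powerlaw`: list with `A`, `B`, `se_A`,
#'   `se_B`, `chisq_nu` (reduced chi-squared, meaningful when `se` given),
#'   `n_used`, `exclude_below`.
#' @export
fit_power_law <- function(P, sigma_theta, se = NULL, exclude_below = 50) {
  stopifnot(length(P) == length(sigma_theta))
  keep <- is.finite(P) & is.finite(sigma_theta) & P >= exclude_below &
    sigma_theta > 0
  if (!is.null(se)) keep <- keep & is.finite(se) & se > 0
  if (sum(keep) < 3)
    stop("insufficient data: need >= 3 points with P >= ", exclude_below,
         " (got ", sum(keep), ")")
  x <- log(P[keep]); y <- log(sigma_theta[keep])
  if (is.null(se)) {
    fit <- stats::lm(y ~ x)
    wts <- rep(1, length(x))
  } else {
    se_log <- se[keep] / sigma_theta[keep]
    wts <- 1 / se_log^2
    fit <- stats::lm(y ~ x, weights = wts)
  }
  cf <- stats::coef(fit)
  vc <- suppressWarnings(stats::vcov(fit))  # exact fits trip summary.lm
  n <- length(x)
  chisq_nu <- sum(wts * stats::residuals(fit)^2) / (n - 2)
  # lm rescales the weighted covariance by the residual variance; undo that
  # to report errors on the absolute scale of the supplied uncertainties
  if (!is.null(se)) vc <- vc / chisq_nu
  structure(list(A = exp(cf[[1]]), B = cf[[2]],
                 se_A = exp(cf[[1]]) * sqrt(vc[1, 1]),
                 se_B = sqrt(vc[2, 2]),
                 chisq_nu = chisq_nu, n_used = n,
                 exclude_below = exclude_below),
            class = "ddf_powerlaw")
}

#' @export
print.ddf_powerlaw <- function(x, ...) {
  cat(sprintf("precision scaling: sigma_theta = A * P^B\n"))
  cat(sprintf("  A = %.4g +/- %.2g   B = %.4g +/- %.2g   (n = %d, P >= %g)\n",
              x$A, x$se_A, x$B, x$se_B, x$n_used, x$exclude_below))
  if (is.finite(x$chisq_nu))
    cat(sprintf("  reduced chi-squared = %.3g\n", x$chisq_nu))
  invisible(x)
}

#' Reference tube angle from two points
#'
#' Angle of the line through two points relative to the horizontal (axial,
#' degrees), with first-order error propagation assuming an independent
#' Gaussian uncertainty of `position_error` pixels (1 sigma) on every
#' coordinate of both points.
#'
#' @param p1,p2 pixel positions `c(x, y)`.
#' @param position_error 1-sigma coordinate uncertainty, pixels (default 2).
#' @return Named vector `c(angle, error)` in degrees.
#' @export
tube_angle_from_points <- function(p1, p2, position_error = 2) {
  stopifnot(length(p1) == 2, length(p2) == 2)
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  L2 <- dx^2 + dy^2
  if (L2 == 0) stop("coincident points")
  angle <- wrap_axial(atan2(dy, dx) * 180 / pi)
  err <- sqrt(2) * position_error / sqrt(L2) * 180 / pi
  c(angle = angle, error = err)
}

#' Square region of interest
#'
#' @param centre pixel position `c(row, col)`.
#' @param size side length in pixels.
#' @return An object of class `ddf_roi`.
#' @export
roi_spec <- function(centre, size) {
  stopifnot(length(centre) == 2, size >= 1)
  structure(list(centre = as.integer(centre), size = as.integer(size)),
            class = "ddf_roi")
}

roi_indices <- function(roi, dims) {
  h <- (roi$size - 1) %/% 2
  rows <- (roi$centre[1] - h):(roi$centre[1] - h + roi$size - 1)
  cols <- (roi$centre[2] - h):(roi$centre[2] - h + roi$size - 1)
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > dims[1] ||
      max(cols) > dims[2])
    stop("ROI extends outside the map")
  list(rows = rows, cols = cols)
}

#' Per-ROI orientation report
#'
#' For each region of interest: the axial mean and standard deviation of the
#' orientation map, and the deviation from orthogonality
#' `<theta> - phi - 90` (wrapped to the axial interval), where `phi` is the
#' reference (fibre/tube) angle.  Anisotropic scatterers are expected to
#' scatter orthogonally to their structural axis, so this deviation measures
#' orientation accuracy.
#'
#' @param theta_map orientation map, degrees.
#' @param rois list of [roi_spec()] objects.
#' @param reference_angles reference angles `phi`, degrees, one per ROI.
#' @param reference_errors optional errors on `phi`, degrees.
#' @param mask optional logical validity mask; an ROI overlapping masked-out
#'   pixels uses only the valid pixels and errors if none are valid.
#' @return Data frame with columns `roi`, `phi_deg`, `phi_err_deg`,
#'   `theta_mean_deg`, `theta_sd_deg`, `deviation_deg`.
#' @export
roi_report <- function(theta_map, rois, reference_angles,
                       reference_errors = NULL, mask = NULL) {
  stopifnot(length(rois) == length(reference_angles))
  if (is.null(reference_errors))
    reference_errors <- rep(NA_real_, length(rois))
  out <- data.frame(roi = seq_along(rois), phi_deg = reference_angles,
                    phi_err_deg = reference_errors,
                    theta_mean_deg = NA_real_, theta_sd_deg = NA_real_,
                    deviation_deg = NA_real_)
  for (i in seq_along(rois)) {
    idx <- roi_indices(rois[[i]], dim(theta_map))
    vals <- theta_map[idx$rows, idx$cols]
    if (!is.null(mask)) {
      ok <- mask[idx$rows, idx$cols]
      vals <- vals[ok]
      if (length(vals) == 0) stop("ROI ", i, " contains no valid pixels")
    }
    st <- axial_mean_sd(as.vector(vals))
    out$theta_mean_deg[i] <- st["mean"]
    out$theta_sd_deg[i] <- st["sd"]
    out$deviation_deg[i] <- wrap_axial(st["mean"] - reference_angles[i] - 90)
  }
  out
}

#' Write an ROI report to CSV
#'
#' @param report a data frame from [roi_report()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_roi_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Polar histogram of axial orientations
#'
#' Bins angles on the axial interval `(-90, 90]`.  The counts sum to the
#' number of (non-missing) input angles.
#'
#' @param angles vector of angles, degrees.
#' @param n_bins number of bins over the 180-degree range (default 36).
#' @return Object of class `ddf_polarhist`: list with `breaks` (degrees),
#'   `mids` and `counts`.
#' @export
polar_histogram <- function(angles, n_bins = 36) {
  angles <- wrap_axial(angles[!is.na(angles)])
  breaks <- seq(-90, 90, length.out = n_bins + 1)
  idx <- findInterval(angles, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[idx == 0] <- 1
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts), class = "ddf_polarhist")
}

#' @export
plot.ddf_polarhist <- function(x, ..., main = "orientation histogram") {
  # axial data: draw each bin twice (theta and theta + 180)
  th <- c(x$mids, x$mids + 180) * pi / 180
  r <- c(x$counts, x$counts)
  rmax <- max(r, 1)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  hw <- pi / length(x$mids) / 2
  for (i in seq_along(th)) {
    a <- seq(th[i] - hw, th[i] + hw, length.out = 8)
    graphics::polygon(c(0, r[i] * cos(a)), c(0, r[i] * sin(a)),
                      col = "grey70", border = "grey30")
  }
  invisible(x)
}
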