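#' speckleddf: directional dark-field retrieval from speckle imaging
#'
#' Speckle-based X-ray imaging records a random intensity pattern (produced by
#' a diffuser such as sandpaper) with and without the sample in the beam, for
#' one or more diffuser positions.  The sample attenuates the pattern
#' (transmittance \eqn{T}), shifts it laterally (refraction, \eqn{u}) and
#' blurs it (ultra-small-angle scattering).  This package models the blur as
#' an anisotropic Gaussian kernel
#' \deqn{K_\alpha(x, y) = A \exp[-\tfrac12(\alpha_1 x^2 + 2\alpha_2 x y +
#'   \alpha_3 y^2)]}
#' and estimates \eqn{(T, u, \alpha)} per pixel by windowed nonlinear least
#' squares over all diffuser positions, giving access to the directional
#' dark-field signal: mean scattering width, directionality and orientation.
#'
#' @section Coordinate and angle conventions:
#' Images are matrices indexed `[row, col]`; `x` is the column coordinate and
#' `y` the row coordinate.  Shifts `u = c(ux, uy)` are (column, row)
#' displacements in pixels.  The kernel orientation `theta` is the axial angle
#' of the *major* (wide) principal axis, measured from the +x axis toward +y,
#' reported in degrees in `(-90, 90]`.  When an image is displayed with row 1
#' at the top (the usual raster convention), a positive `theta` therefore
#' appears as a clockwise rotation on screen; display with row 1 at the
#' bottom (y up) to see angles counter-clockwise.
#'
#' @docType package
#' @name speckleddf-package
#' @aliases speckleddf
#' @useDynLib speckleddf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

DELTA_FLOOR <- 0.05  # widths (px) below this behave as a discrete delta
ISO_ECC_EPS <- 0.02  # below this eccentricity theta is reported as 0/flagged

#' Anisotropic Gaussian blur-kernel parameters
#'
#' The triple \eqn{\alpha = (\alpha_1, \alpha_2, \alpha_3)} defines the
#' inverse-covariance quadratic form of the scattering kernel.  The matrix
#' \eqn{[[\alpha_1, \alpha_2], [\alpha_2, \alpha_3]]} must be positive
#' definite for the kernel to be normalisable.
#'
#' @param alpha1,alpha2,alpha3 kernel parameters, inverse square pixels.
#' @return An object of class `ddf_kernel_params`.
#' @examples
#' blur_kernel(2, 1, 2)
#' @export
blur_kernel <- function(alpha1, alpha2, alpha3) {
  stopifnot(is.numeric(alpha1), is.numeric(alpha2), is.numeric(alpha3),
            length(alpha1) == 1, length(alpha2) == 1, length(alpha3) == 1)
  if (!(alpha1 > 0))
    stop("invalid kernel: alpha1 > 0 violated (alpha1 = ", alpha1, ")")
  if (!(alpha3 > 0))
    stop("invalid kernel: alpha3 > 0 violated (alpha3 = ", alpha3, ")")
  if (!(alpha1 * alpha3 - alpha2^2 > 0))
    stop("invalid kernel: alpha1*alpha3 - alpha2^2 > 0 violated ",
         "(value = ", alpha1 * alpha3 - alpha2^2, ")")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3),
            class = "ddf_kernel_params")
}

#' @export
print.ddf_kernel_params <- function(x, ...) {
  ax <- alpha_to_axes(x)
  cat(sprintf("blur kernel: alpha = (%.4g, %.4g, %.4g)\n",
              x$alpha1, x$alpha2, x$alpha3))
  cat(sprintf("  sigma_major = %.4g px, sigma_minor = %.4g px, theta = %.2f deg\n",
              ax$sigma_major, ax$sigma_minor, ax$theta))
  invisible(x)
}

as_kernel_params <- function(p) {
  if (inherits(p, "ddf_kernel_params")) return(p)
  if (is.numeric(p) && length(p) == 3) return(blur_kernel(p[1], p[2], p[3]))
  stop("expected a ddf_kernel_params object or a numeric triple")
}

#' Rasterise the blur kernel on a pixel grid
#'
#' Samples the anisotropic Gaussian on an odd-sized grid centred at the
#' origin and normalises to unit sum, so that convolution preserves the image
#' mean and the transmittance stays a pure attenuation factor.  Sampling is
#' moment-matched: the sampling covariance is adjusted iteratively so the
#' discrete second moments of the raster equal the continuous kernel
#' covariance (the inverse of the alpha matrix); plain point sampling would
#' underestimate sub-pixel widths.  Widths below 0.05 px are treated as a
#' discrete delta (no blur).
#'
#' @param params a [blur_kernel()] object (or numeric triple).
#' @param support_radius grid half-size in pixels, or `NULL` for the
#'   automatic choice `ceiling(4 * sigma_major)` (under 0.1% mass loss).
#' @return An object of class `ddf_kernel_image`: list with `weights` (an
#'   odd-sized matrix summing to 1, `weights[iy + R + 1, ix + R + 1]` is the
#'   weight at offset `(x = ix, y = iy)`) and `support_radius`.
#' @examples
#' k <- evaluate_kernel(blur_kernel(1, 0, 1), support_radius = 5)
#' sum(k$weights)
#' @export
evaluate_kernel <- function(params, support_radius = NULL) {
  p <- as_kernel_params(params)
  r <- if (is.null(support_radius)) -1L else as.integer(support_radius)
  if (!is.null(support_radius) && r < 1)
    stop("support_radius must be >= 1")
  w <- cpp_rasterize_kernel(p$alpha1, p$alpha2, p$alpha3, r)
  structure(list(weights = w, support_radius = (nrow(w) - 1L) %/% 2L),
            class = "ddf_kernel_image")
}

#' Principal axes of a blur kernel
#'
#' Converts the inverse-covariance parameters into principal widths and the
#' axial orientation of the wide axis: `sigma_major = 1/sqrt(lambda_min)`,
#' `sigma_minor = 1/sqrt(lambda_max)` for eigenvalues `lambda` of the alpha
#' matrix, and `theta = 0.5 * atan2(-2 alpha2, alpha3 - alpha1)` degrees in
#' `(-90, 90]` (see the package conventions).  Near-isotropic kernels
#' (eccentricity below 0.02) report `theta = 0` with `isotropic = TRUE`.
#'
#' @param params a [blur_kernel()] object (or numeric triple).
#' @return An object of class `ddf_axes`: list with `sigma_major`,
#'   `sigma_minor` (pixels), `theta` (degrees) and `isotropic` flag.
#' @examples
#' alpha_to_axes(blur_kernel(4, 0, 1))  # sigma 1 x 0.5, theta 90
#' @export
alpha_to_axes <- function(params) {
  p <- as_kernel_params(params)
  a1 <- p$alpha1; a2 <- p$alpha2; a3 <- p$alpha3
  tr <- a1 + a3
  disc <- sqrt((a1 - a3)^2 + 4 * a2^2)
  lmax <- (tr + disc) / 2
  lmin <- (tr - disc) / 2
  ecc <- disc / tr
  iso <- ecc < ISO_ECC_EPS
  # theta is undefined only at exact isotropy; the <0.02 isotropy *flag* is
  # advisory (map-level outputs zero flagged orientations, this conversion
  # stays exactly invertible)
  theta <- if (disc <= 1e-14 * tr) 0
           else wrap_axial(0.5 * atan2(-2 * a2, a3 - a1) * 180 / pi)
  principal_axes(1 / sqrt(lmin), 1 / sqrt(lmax), theta, isotropic = iso)
}

principal_axes <- function(sigma_major, sigma_minor, theta, isotropic = FALSE) {
  structure(list(sigma_major = sigma_major, sigma_minor = sigma_minor,
                 theta = theta, isotropic = isotropic), class = "ddf_axes")
}

#' @export
print.ddf_axes <- function(x, ...) {
  cat(sprintf("kernel axes: sigma_major = %.4g px, sigma_minor = %.4g px, theta = %.2f deg%s\n",
              x$sigma_major, x$sigma_minor, x$theta,
              if (isTRUE(x$isotropic)) " (isotropic)" else ""))
  invisible(x)
}

#' Blur-kernel parameters from principal axes
#'
#' Inverse of [alpha_to_axes()]: builds the alpha triple whose kernel has
#' widths `sigma_major` along `theta` and `sigma_minor` across.
#'
#' @param sigma_major,sigma_minor principal widths in pixels
#'   (`sigma_major >= sigma_minor > 0`), or a `ddf_axes` object as the first
#'   argument.
#' @param theta axial orientation of the major axis, degrees.
#' @return A [blur_kernel()] object.
#' @examples
#' axes_to_alpha(1, 0.5, 90)  # alpha = (4, 0, 1)
#' @export
axes_to_alpha <- function(sigma_major, sigma_minor = NULL, theta = NULL) {
  if (inherits(sigma_major, "ddf_axes")) {
    a <- sigma_major
    sigma_major <- a$sigma_major; sigma_minor <- a$sigma_minor
    theta <- a$theta
  }
  if (!(sigma_minor > 0) || !(sigma_major > 0))
    stop("kernel widths must be strictly positive")
  if (sigma_major < sigma_minor)
    stop("sigma_major must be >= sigma_minor")
  th <- theta * pi / 180
  c2 <- cos(th); s2 <- sin(th)
  va <- sigma_major^2; vb <- sigma_minor^2
  cxx <- va * c2^2 + vb * s2^2
  cyy <- va * s2^2 + vb * c2^2
  cxy <- (va - vb) * s2 * c2
  det <- va * vb
  blur_kernel(cyy / det, -cxy / det, cxx / det)
}

#' Imaging geometry
#'
#' @param pixel_size detector pixel size in the sample plane, metres.
#'   Default 21.5e-6 m (the synchrotron full-field geometry used throughout
#'   the documentation).
#' @param distance_d sample-to-detector propagation distance, metres
#'   (default 6.65 m).
#' @return An object of class `ddf_geometry`.
#' @export
geometry_spec <- function(pixel_size = 21.5e-6, distance_d = 6.65) {
  stopifnot(pixel_size > 0, distance_d > 0)
  structure(list(pixel_size = pixel_size, distance_d = distance_d),
            class = "ddf_geometry")
}

#' Paired sample/reference speckle frame stacks
#'
#' @param sample,reference 3-D arrays `[H, W, N]` (or single matrices) of
#'   non-negative intensities; one slice per diffuser position.
#' @param geometry a [geometry_spec()].
#' @return An object of class `ddf_frames` with elements `sample`,
#'   `reference`, `n_positions`, `geometry`.
#' @export
speckle_frame_set <- function(sample, reference, geometry = geometry_spec()) {
  as_stack <- function(a, what) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    if (!is.array(a) || length(dim(a)) != 3)
      stop(what, " must be a matrix or a [H, W, N] array")
    storage.mode(a) <- "double"
    a
  }
  sample <- as_stack(sample, "sample")
  reference <- as_stack(reference, "reference")
  if (!identical(dim(sample), dim(reference)))
    stop("sample and reference stacks must have identical shape (got ",
         paste(dim(sample), collapse = "x"), " vs ",
         paste(dim(reference), collapse = "x"), ")")
  if (anyNA(sample) || anyNA(reference) ||
      !all(is.finite(sample)) || !all(is.finite(reference)))
    stop("frame intensities must be finite")
  if (min(sample) < 0 || min(reference) < 0)
    stop("frame intensities must be non-negative")
  stopifnot(inherits(geometry, "ddf_geometry"))
  structure(list(sample = sample, reference = reference,
                 n_positions = dim(sample)[3], geometry = geometry),
            class = "ddf_frames")
}

#' @export
print.ddf_frames <- function(x, ...) {
  d <- dim(x$sample)
  cat(sprintf("speckle frame set: %d x %d pixels, N = %d diffuser positions\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Forward image-formation model on a full frame
#'
#' Applies the model `T * (reference (*) K_alpha)(r + u)`: the reference is
#' convolved with the rasterised kernel, sampled at r + u with cubic
#' (Catmull-Rom) interpolation using mirror boundary handling, and scaled by
#' the transmittance.  Interpolation undershoot is clipped at zero.
#'
#' @param reference_frame non-negative intensity matrix.
#' @param transmittance scalar `T >= 0`.
#' @param u shift `c(ux, uy)` in pixels (column, row); must be smaller than
#'   the frame margins.
#' @param params a [blur_kernel()] object.
#' @param max_shift declared maximum |shift| (default: a quarter of the
#'   smaller frame side); larger shifts are refused.
#' @return The modelled intensity matrix, same size as the input.
#' @export
model_intensity <- function(reference_frame, transmittance, u, params,
                            max_shift = NULL) {
  stopifnot(is.matrix(reference_frame), transmittance >= 0,
            length(u) == 2, all(is.finite(u)))
  if (is.null(max_shift)) max_shift <- min(dim(reference_frame)) / 4
  if (max(abs(u)) > max_shift)
    stop("shift ", max(abs(u)), " px exceeds the declared maximum of ",
         max_shift, " px")
  p <- as_kernel_params(params)
  cpp_model_intensity(reference_frame, transmittance, u[1], u[2],
                      p$alpha1, p$alpha2, p$alpha3, -1L)
}

# wrap angles (degrees) to the axial interval (-90, 90]
wrap_axial <- function(x) {
  w <- ((x + 90) %% 180) - 90
  w[w <= -90] <- 90
  w
}
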