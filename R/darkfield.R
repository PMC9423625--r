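#' Derived dark-field summary: mean width, directionality, orientation
#'
#' Converts kernel parameters into the three dark-field observables:
#' \itemize{
#'   \item mean kernel width
#'     \eqn{\sigma^2 = \tfrac12(\sigma_M^2+\sigma_m^2)
#'          = \tfrac12(\alpha_1+\alpha_3)/(\alpha_1\alpha_3-\alpha_2^2)},
#'   \item directionality
#'     \eqn{\varepsilon = (\sigma_M^2-\sigma_m^2)/(\sigma_M^2+\sigma_m^2)
#'          = \sqrt{(\alpha_3-\alpha_1)^2+4\alpha_2^2}/(\alpha_1+\alpha_3)},
#'   \item orientation \eqn{\theta} of the wide axis (degrees, axial), using
#'     the same convention as [alpha_to_axes()].
#' }
#' The directionality is 0 for isotropic scattering and approaches 1 for
#' strongly directional scattering; pixels with `eccentricity < 0.02` are
#' flagged isotropic and report `theta = 0`.
#'
#' @param params a [blur_kernel()] object, a numeric triple, or a
#'   `ddf_signal_maps` object (vectorised over the alpha maps).
#' @return For kernel parameters: a list `sigma`, `eccentricity`, `theta`,
#'   `isotropic`.  For signal maps: the same fields as matrices plus an
#'   `isotropic` companion mask (class `ddf_darkfield`).
#' @examples
#' darkfield_summary(blur_kernel(4, 0, 1))  # sigma^2 = 0.625, ecc 0.6, 90 deg
#' @export
darkfield_summary <- function(params) {
  if (inherits(params, "ddf_signal_maps")) {
    s <- df_from_alpha(params$a1, params$a2, params$a3)
    s$isotropic[!params$mask] <- NA
    return(structure(c(s, list(mask = params$mask)), class = "ddf_darkfield"))
  }
  p <- as_kernel_params(params)
  df_from_alpha(p$alpha1, p$alpha2, p$alpha3)
}

df_from_alpha <- function(a1, a2, a3) {
  det <- a1 * a3 - a2^2
  sigma <- sqrt(0.5 * (a1 + a3) / det)
  ecc <- sqrt((a3 - a1)^2 + 4 * a2^2) / (a1 + a3)
  theta <- wrap_axial(0.5 * atan2(-2 * a2, a3 - a1) * 180 / pi)
  iso <- ecc < ISO_ECC_EPS
  theta[iso & !is.na(iso)] <- 0
  list(sigma = sigma, eccentricity = ecc, theta = theta, isotropic = iso)
}

#' Refraction-angle maps
#'
#' Converts the recovered speckle shifts into refraction angles
#' `u * pixel_size / distance_d`, reported in microradians.
#'
#' @param maps a `ddf_signal_maps` object (or any list with `ux`, `uy`).
#' @param geometry a [geometry_spec()].
#' @return List with `angle_x` and `angle_y` matrices in microradians.
#' @examples
#' g <- geometry_spec(21.5e-6, 6.65)
#' refraction_maps(list(ux = matrix(1), uy = matrix(0)), g)$angle_x # ~3.23
#' @export
refraction_maps <- function(maps, geometry) {
  stopifnot(inherits(geometry, "ddf_geometry"))
  f <- geometry$pixel_size / geometry$distance_d * 1e6
  list(angle_x = maps$ux * f, angle_y = maps$uy * f)
}

#' HSV composite of the directional dark-field signal
#'
#' Combines the three dark-field maps into one colour image: hue encodes the
#' scattering orientation (`H = (theta + 90) / 180`, axially continuous:
#' -90 deg and +90 deg map to the same hue), saturation the directionality
#' (clipped to `[0, 1]`), and value the mean kernel width normalised by a
#' percentile clip.  Pixels with no dark-field therefore appear dark, and
#' isotropic scatterers grey.
#'
#' @param theta orientation map, degrees in `(-90, 90]`.
#' @param eccentricity directionality map in `[0, 1)`.
#' @param sigma mean kernel width map, pixels.
#' @param value_clip percentile (0-1] used to normalise `sigma` for display
#'   (default 0.99).
#' @return An `[H, W, 3]` array of RGB values in `[0, 1]`; `NA` pixels render
#'   black.
#' @export
hsv_composite <- function(theta, eccentricity, sigma, value_clip = 0.99) {
  stopifnot(identical(dim(theta), dim(eccentricity)),
            identical(dim(theta), dim(sigma)),
            value_clip > 0, value_clip <= 1)
  h <- (wrap_axial(theta) + 90) / 180
  h[h >= 1] <- 0  # hue is circular: theta = +90 == -90
  s <- pmin(pmax(eccentricity, 0), 1)
  vref <- stats::quantile(sigma, probs = value_clip, na.rm = TRUE,
                          names = FALSE)
  v <- if (is.finite(vref) && vref > 0) pmin(pmax(sigma / vref, 0), 1)
       else sigma * 0
  bad <- !is.finite(h) | !is.finite(s) | !is.finite(v)
  h[bad] <- 0; s[bad] <- 0; v[bad] <- 0
  # vectorised HSV -> RGB
  hh <- h * 6
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dim = c(dim(theta), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
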