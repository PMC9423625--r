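# Synthetic near-field speckle: the test bed standing in for beamline data.

# run code with a private, restored RNG state seeded deterministically
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Speckle pattern specification
#'
#' @param shape image size `c(H, W)` in pixels.
#' @param speckle_size target autocorrelation FWHM in pixels (default 3; the
#'   physical diffusers this emulates do not come with a published speckle
#'   size, so this is a declared package default).
#' @param visibility target std/mean (default 0.3, declared default).
#' @param mean_counts mean photons per pixel (default 1e4).
#' @param seed integer RNG seed.
#' @return An object of class `ddf_pattern_spec`.
#' @export
pattern_spec <- function(shape, speckle_size = 3, visibility = 0.3,
                         mean_counts = 1e4, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 8), speckle_size >= 1,
            visibility > 0, visibility < 1, mean_counts > 0)
  structure(list(shape = as.integer(shape), speckle_size = speckle_size,
                 visibility = visibility, mean_counts = mean_counts,
                 seed = as.integer(seed)), class = "ddf_pattern_spec")
}

#' Generate a synthetic near-field speckle pattern
#'
#' Band-limited white noise: a Gaussian random field is smoothed with an
#' isotropic Gaussian whose width is chosen so the autocorrelation FWHM of
#' the result matches `speckle_size`, then affinely mapped to the requested
#' mean and visibility (std/mean) and clipped at zero.  Deterministic per
#' seed.
#'
#' @param spec a [pattern_spec()].
#' @return A non-negative intensity matrix.
#' @export
generate_speckle_pattern <- function(spec) {
  stopifnot(inherits(spec, "ddf_pattern_spec"))
  with_seed(spec$seed, {
    z <- matrix(stats::rnorm(prod(spec$shape)), spec$shape[1], spec$shape[2])
    # smoothing an uncorrelated field with a Gaussian of width s gives an
    # autocorrelation of width s*sqrt(2); FWHM = 2.3548 * s * sqrt(2)
    s <- spec$speckle_size / (2 * sqrt(2 * log(2)) * sqrt(2))
    if (s >= DELTA_FLOOR) {
      k <- evaluate_kernel(axes_to_alpha(s, s, 0))
      z <- cpp_convolve(z, k$weights)
    }
    z <- (z - mean(z)) / stats::sd(z)
    img <- spec$mean_counts * (1 + spec$visibility * z)
    img[img < 0] <- 0
    img <- img * (spec$mean_counts / mean(img))  # exact mean after clipping
    img
  })
}

#' Spiral diffuser positions
#'
#' Offsets along a sunflower (Vogel) spiral: radius proportional to the
#' square root of the index, golden-angle increments.  This emulates moving
#' the diffuser in a spiral so that no two positions share an x or a y
#' component and all pairwise distances are at least `step`.
#'
#' @param n number of positions.
#' @param step minimum pairwise distance in pixels (should exceed the speckle
#'   size).
#' @return An `n x 2` matrix of `(x, y)` offsets; the first row is `(0, 0)`.
#' @export
spiral_positions <- function(n, step) {
  stopifnot(n >= 1, step > 0)
  k <- seq_len(n) - 1
  golden <- pi * (3 - sqrt(5))
  # 0.01 rad tilt avoids axis-aligned first step (distinct x and y)
  ang <- k * golden + 0.01
  r <- step * sqrt(k)
  pos <- cbind(x = r * cos(ang), y = r * sin(ang))
  if (n > 1) {
    dmin <- min(stats::dist(pos))
    if (dmin < step) pos <- pos * (step / dmin)
    # nudge any coincident coordinates (cannot occur for the golden angle,
    # kept as a guard for pathological n)
    for (cmp in 1:2) {
      while (anyDuplicated(round(pos[, cmp], 9)) > 0)
        pos[, cmp] <- pos[, cmp] + stats::runif(n, -1e-6, 1e-6)
    }
  }
  pos
}

#' Phantom specification: regionwise (T, u, kernel) fields
#'
#' @param labels integer matrix of region labels (0 = background).
#' @param regions data frame with one row per label present in `labels`
#'   (including 0 if present) and columns `label`, `T`, `ux`, `uy`,
#'   `sigma_major`, `sigma_minor`, `theta`.
#' @return An object of class `ddf_phantom`.
#' @export
phantom_spec <- function(labels, regions) {
  stopifnot(is.matrix(labels),
            all(c("label", "T", "ux", "uy", "sigma_major", "sigma_minor",
                  "theta") %in% names(regions)))
  present <- sort(unique(as.vector(labels)))
  if (!all(present %in% regions$label))
    stop("labels ", paste(setdiff(present, regions$label), collapse = ", "),
         " have no region parameters")
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!(r$T >= 0)) stop("region ", r$label, ": T must be >= 0")
    if (r$sigma_major > DELTA_FLOOR)  # validates positive definiteness
      axes_to_alpha(r$sigma_major, r$sigma_minor, r$theta)
  }
  structure(list(labels = labels, regions = regions), class = "ddf_phantom")
}

#' Four-tube phantom preset
#'
#' Emulates four unidirectional-fibre tube pieces arranged so the fibres run
#' vertically, horizontally and along both diagonals, one per quadrant.
#' Fibres scatter orthogonally to their axis, so the true kernel orientation
#' in each quadrant is the fibre angle + 90 degrees.  Default regions use
#' `T = 0.8`, widths (2, 1) px (directionality 0.6) and small distinct
#' sub-pixel shifts.
#'
#' @param shape phantom size `c(H, W)`.
#' @param fibre_angles fibre axis angles (degrees) of the four quadrants,
#'   clockwise from top-left.
#' @param sigma widths `c(major, minor)` of the scattering kernel.
#' @param transmittance regional transmittance.
#' @return A [phantom_spec()] whose `regions` carry the extra column
#'   `fibre_angle` (the reference angle phi for orientation analysis).
#' @export
four_tube_phantom <- function(shape = c(256, 256),
                              fibre_angles = c(90, 0, 45, -45),
                              sigma = c(2, 1), transmittance = 0.8) {
  stopifnot(length(shape) == 2, length(fibre_angles) == 4)
  H <- shape[1]; W <- shape[2]
  labels <- matrix(0L, H, W)
  labels[seq_len(ceiling(H / 2)), seq_len(ceiling(W / 2))] <- 1L
  labels[seq_len(ceiling(H / 2)), (ceiling(W / 2) + 1):W] <- 2L
  labels[(ceiling(H / 2) + 1):H, seq_len(ceiling(W / 2))] <- 3L
  labels[(ceiling(H / 2) + 1):H, (ceiling(W / 2) + 1):W] <- 4L
  shifts <- matrix(c(0.6, -0.4, -0.5, 0.3, 0.2, 0.5, -0.3, -0.6),
                   ncol = 2, byrow = TRUE)
  regions <- data.frame(
    label = 1:4,
    T = transmittance,
    ux = shifts[, 1], uy = shifts[, 2],
    sigma_major = sigma[1], sigma_minor = sigma[2],
    theta = wrap_axial(fibre_angles + 90),
    fibre_angle = fibre_angles)
  phantom_spec(labels, regions)
}

#' Acquisition specification
#'
#' @param n_positions number of diffuser positions N (default 25).
#' @param step diffuser step in pixels (default 8; must exceed the speckle
#'   size when `n_positions > 1`).
#' @param n_reference_averages exposures averaged per reference frame
#'   (default 50).
#' @param noise apply Poisson counting noise (default TRUE).
#' @param seed integer RNG seed for the noise draws.
#' @return An object of class `ddf_acquisition`.
#' @export
acquisition_spec <- function(n_positions = 25, step = 8,
                             n_reference_averages = 50, noise = TRUE,
                             seed = 1L) {
  stopifnot(n_positions >= 1, step > 0, n_reference_averages >= 1)
  structure(list(n_positions = as.integer(n_positions), step = step,
                 n_reference_averages = as.integer(n_reference_averages),
                 noise = isTRUE(noise), seed = as.integer(seed)),
            class = "ddf_acquisition")
}

#' Synthesise a speckle dataset with known ground truth
#'
#' For each diffuser position the reference frame is a crop of the master
#' pattern at the (rounded) spiral offset, averaged over
#' `n_reference_averages` independent Poisson draws; the sample frame applies
#' the forward model regionwise (transmittance, shift, anisotropic blur) to
#' the same crop, with a single Poisson draw.  Ground-truth maps are
#' returned alongside, co-registered with the frames.
#'
#' @param pattern master speckle pattern: either a matrix larger than the
#'   phantom by twice the required margin (spiral extent + kernel support +
#'   shift), or a [pattern_spec()] from which one is generated.
#' @param phantom a [phantom_spec()].
#' @param acq an [acquisition_spec()].
#' @param geometry a [geometry_spec()].
#' @return List with `frames` (a [speckle_frame_set()]), `truth` (matrices
#'   `T`, `ux`, `uy`, `a1`, `a2`, `a3`, `sigma`, `eccentricity`, `theta`,
#'   `labels`) and `offsets`.
#' @export
synthesize_dataset <- function(pattern, phantom, acq = acquisition_spec(),
                               geometry = geometry_spec()) {
  stopifnot(inherits(phantom, "ddf_phantom"), inherits(acq, "ddf_acquisition"))
  H <- nrow(phantom$labels); W <- ncol(phantom$labels)
  regs <- phantom$regions
  rmax <- max(1, ceiling(4 * max(regs$sigma_major)))
  umax <- ceiling(max(abs(c(regs$ux, regs$uy)), 0))
  offsets <- round(spiral_positions(acq$n_positions, acq$step))
  omax <- max(abs(offsets), 0)
  border <- as.integer(rmax + umax + 2)
  need <- c(H, W) + 2 * (omax + border)

  if (inherits(pattern, "ddf_pattern_spec")) {
    if (acq$n_positions > 1 && acq$step <= pattern$speckle_size)
      warning("diffuser step (", acq$step,
              " px) does not exceed the speckle size (",
              pattern$speckle_size, " px)")
    spec <- pattern
    spec$shape <- as.integer(need)
    master <- generate_speckle_pattern(spec)
  } else {
    master <- pattern
    if (nrow(master) < need[1] || ncol(master) < need[2])
      stop("master pattern ", nrow(master), "x", ncol(master),
           " too small: need at least ", need[1], "x", need[2],
           " (phantom + 2*(spiral extent ", omax, " + margin ", border, "))")
  }
  cy <- floor((nrow(master) - H) / 2)  # top-left of the central crop
  cx <- floor((ncol(master) - W) / 2)

  truthT <- matrix(NA_real_, H, W); tux <- truthT; tuy <- truthT
  ta1 <- truthT; ta2 <- truthT; ta3 <- truthT
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    sel <- phantom$labels == r$label
    truthT[sel] <- r$T; tux[sel] <- r$ux; tuy[sel] <- r$uy
    if (r$sigma_major <= DELTA_FLOOR) {
      al <- c(1e4, 0, 1e4)  # delta kernel
    } else {
      p <- axes_to_alpha(r$sigma_major, max(r$sigma_minor, 1e-3), r$theta)
      al <- c(p$alpha1, p$alpha2, p$alpha3)
    }
    ta1[sel] <- al[1]; ta2[sel] <- al[2]; ta3[sel] <- al[3]
  }

  sample <- array(0, dim = c(H, W, acq$n_positions))
  reference <- array(0, dim = c(H, W, acq$n_positions))
  with_seed(acq$seed, {
    for (j in seq_len(acq$n_positions)) {
      oy <- offsets[j, 2]; ox <- offsets[j, 1]
      rows <- (cy + oy - border + 1):(cy + oy + H + border)
      cols <- (cx + ox - border + 1):(cx + ox + W + border)
      ext <- master[rows, cols]                 # extended clean reference
      inner <- (border + 1):(border + H)
      clean_ref <- ext[inner, (border + 1):(border + W)]
      clean_sam <- matrix(0, H, W)
      for (i in seq_len(nrow(regs))) {
        r <- regs[i, ]
        sel <- phantom$labels == r$label
        if (!any(sel)) next
        if (r$sigma_major <= DELTA_FLOOR && r$ux == 0 && r$uy == 0) {
          mod <- r$T * clean_ref
        } else {
          p <- if (r$sigma_major <= DELTA_FLOOR)
            blur_kernel(1e4, 0, 1e4) else
            axes_to_alpha(r$sigma_major, max(r$sigma_minor, 1e-3), r$theta)
          modext <- cpp_model_intensity(ext, r$T, r$ux, r$uy,
                                        p$alpha1, p$alpha2, p$alpha3, -1L)
          mod <- modext[inner, (border + 1):(border + W)]
        }
        clean_sam[sel] <- mod[sel]
      }
      if (acq$noise) {
        sample[, , j] <- matrix(stats::rpois(H * W, clean_sam), H, W)
        acc <- matrix(0, H, W)
        for (k in seq_len(acq$n_reference_averages))
          acc <- acc + matrix(stats::rpois(H * W, clean_ref), H, W)
        reference[, , j] <- acc / acq$n_reference_averages
      } else {
        sample[, , j] <- clean_sam
        reference[, , j] <- clean_ref
      }
    }
  })
  df <- df_from_alpha(ta1, ta2, ta3)
  list(frames = speckle_frame_set(sample, reference, geometry),
       truth = list(T = truthT, ux = tux, uy = tuy,
                    a1 = ta1, a2 = ta2, a3 = ta3,
                    sigma = df$sigma, eccentricity = df$eccentricity,
                    theta = df$theta, labels = phantom$labels),
       offsets = offsets)
}
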