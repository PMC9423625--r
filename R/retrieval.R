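#' Hamming analysis window
#'
#' Tapered weights localising the least-squares fit around each pixel: the
#' separable product of two 1-D Hamming windows, rescaled so the central
#' weight is 1.
#'
#' @param size odd side length in pixels, `>= 3`.
#' @return An object of class `ddf_window`: list with `size` and `weights`.
#' @export
hamming_window <- function(size) {
  size <- as.integer(size)
  if (size < 3 || size %% 2 == 0)
    stop("window size must be odd and >= 3 (got ", size, ")")
  n <- seq_len(size) - 1
  h <- 0.54 - 0.46 * cos(2 * pi * n / (size - 1))
  w <- outer(h, h)
  w <- w / max(w)
  structure(list(size = size, weights = w), class = "ddf_window")
}

as_window <- function(w) {
  if (inherits(w, "ddf_window")) return(w)
  if (is.numeric(w) && length(w) == 1) return(hamming_window(w))
  if (is.matrix(w)) {
    if (nrow(w) != ncol(w) || nrow(w) %% 2 == 0)
      stop("window weight matrix must be square with odd side")
    if (max(w) != 1 || w[(nrow(w) + 1) / 2, (nrow(w) + 1) / 2] <= 0)
      stop("window weights must have max 1 and a positive centre")
    return(structure(list(size = nrow(w), weights = w), class = "ddf_window"))
  }
  stop("expected a ddf_window, an odd size, or a weight matrix")
}

#' Solver configuration
#'
#' @param window analysis window: a [hamming_window()], an odd size, or a
#'   weight matrix.  Default 7x7 Hamming (sizes up to 31x31 are routinely
#'   used; larger windows trade spatial resolution for orientation
#'   precision).
#' @param levels multi-resolution binning factors, coarse to fine, strictly
#'   decreasing, last = 1.  Default `c(4, 2, 1)`.
#' @param max_shift maximum |u| component in pixels (default 5).
#' @param width_bounds kernel width search range in pixels,
#'   `c(min, max)` (default `c(0.02, 3)`); the upper bound also caps the
#'   kernel support and hence the excluded margin.
#' @param step solve-grid stride at the finest level (default 1 = every
#'   pixel).  Coarser levels use `max(1, round(step / level))`.  Pixels off
#'   the stride grid are left masked.
#' @param cost_tol relative simplex-spread tolerance for convergence
#'   (default 1e-7).
#' @param param_tol simplex-extent stop in parameter units (pixels / log
#'   width / radians; default 1e-3, well below the statistical noise floor
#'   of any realistic acquisition).
#' @param max_eval cost-evaluation budget per pixel refinement (default 400).
#' @param grid_widths isotropic width grid (px) for the coarse-level
#'   exhaustive initialisation; 0 means a delta kernel.
#' @param seed integer seed recorded with results (the solver itself is
#'   deterministic; the seed also drives any stochastic synthesis run under
#'   this configuration).
#' @return An object of class `ddf_config`.
#' @export
solver_config <- function(window = 7, levels = c(4, 2, 1), max_shift = 5,
                          width_bounds = c(0.02, 3), step = 1L,
                          cost_tol = 1e-7, param_tol = 1e-3,
                          max_eval = 400L,
                          grid_widths = c(0, 0.5, 1, 2), seed = 1L) {
  window <- as_window(window)
  levels <- as.integer(levels)
  if (length(levels) < 1)
    stop("at least one level is required")
  if (length(levels) > 1 && any(diff(levels) >= 0))
    stop("levels must be strictly decreasing")
  if (levels[length(levels)] != 1L)
    stop("the last level must be 1 (full resolution)")
  stopifnot(max_shift >= 0, length(width_bounds) == 2,
            width_bounds[1] > 0, width_bounds[2] > width_bounds[1],
            step >= 1, cost_tol > 0, param_tol >= 0, max_eval >= 10)
  structure(list(window = window, levels = levels, max_shift = max_shift,
                 width_bounds = width_bounds, step = as.integer(step),
                 cost_tol = cost_tol, param_tol = param_tol,
                 max_eval = as.integer(max_eval),
                 grid_widths = grid_widths, seed = as.integer(seed)),
            class = "ddf_config")
}

# excluded border width for a given window/config at one level
solver_margin <- function(window_size, max_shift, width_max) {
  radius_cap <- max(1L, as.integer(ceiling(4 * width_max)))
  as.integer((window_size - 1) / 2 + ceiling(max_shift) + radius_cap + 2L)
}

KCUT_SOLVER <- 1e-7  # relative kernel-tap cutoff inside the search only

#' Windowed least-squares cost at one pixel
#'
#' The double sum over the window and all frame pairs of
#' `Gamma(r - r0) * (I_j(r) - T * (I0_j (*) K_alpha)(r + u))^2`.
#'
#' @param frames a [speckle_frame_set()].
#' @param r0 pixel position `c(row, col)`, 1-based.
#' @param transmittance scalar `T`, or `NA` to use the closed-form optimum.
#' @param u shift `c(ux, uy)` in pixels.
#' @param params a [blur_kernel()] object.
#' @param window window spec (see [hamming_window()]), default 7.
#' @return The scalar cost (intensity-squared units), with the transmittance
#'   actually used as attribute `"T"`.
#' @export
cost_function <- function(frames, r0, transmittance, u, params, window = 7) {
  stopifnot(inherits(frames, "ddf_frames"), length(r0) == 2)
  w <- as_window(window)
  p <- as_kernel_params(params)
  res <- cpp_cost(frames$sample, frames$reference,
                  as.integer(r0[1]) - 1L, as.integer(r0[2]) - 1L,
                  w$weights, as.numeric(transmittance), u[1], u[2],
                  p$alpha1, p$alpha2, p$alpha3, -1L)
  structure(res$cost, T = res$T)
}

#' Closed-form optimal transmittance
#'
#' The cost is quadratic in `T`; its minimiser is
#' `T* = sum(Gamma I M) / sum(Gamma M^2)` with `M` the modelled (blurred,
#' shifted) reference.
#'
#' @inheritParams cost_function
#' @return The scalar `T*`.
#' @export
optimal_transmission <- function(frames, r0, u, params, window = 7) {
  stopifnot(inherits(frames, "ddf_frames"), length(r0) == 2)
  w <- as_window(window)
  p <- as_kernel_params(params)
  res <- cpp_cost(frames$sample, frames$reference,
                  as.integer(r0[1]) - 1L, as.integer(r0[2]) - 1L,
                  w$weights, NA_real_, u[1], u[2],
                  p$alpha1, p$alpha2, p$alpha3, -1L)
  if (!is.finite(res$T))
    stop("degenerate window: model term vanishes, T* undefined")
  res$T
}

#' Solve the model at a single pixel
#'
#' Minimises the windowed cost over `(T, ux, uy, alpha)` at one pixel.
#' Positive definiteness is guaranteed by optimising in
#' `(log sigma_major, log sigma_minor, theta)`; `T` is eliminated in closed
#' form at every cost evaluation.  The search is a deterministic Nelder-Mead
#' started from `init` (or from an exhaustive integer-shift x isotropic-width
#' grid when `init` is `NULL`); the returned cost never exceeds the cost at
#' the initial point.
#'
#' @inheritParams cost_function
#' @param config a [solver_config()].
#' @param init optional initial solution: a list with `u` and `params`
#'   (kernel), e.g. a previous pixel solution.
#' @return An object of class `ddf_pixel_solution`: list with
#'   `transmittance`, `u`, `params`, `residual`, `converged`, `n_eval`.
#' @export
solve_pixel <- function(frames, r0, window = NULL, config = solver_config(),
                        init = NULL) {
  stopifnot(inherits(frames, "ddf_frames"), inherits(config, "ddf_config"))
  w <- if (is.null(window)) config$window else as_window(window)
  if (any(!is.finite(frames$sample)) || any(!is.finite(frames$reference)))
    stop("non-finite intensities in the frame set")
  qinit <- numeric(0)
  if (!is.null(init)) {
    p <- as_kernel_params(init$params)
    ax <- alpha_to_axes(p)
    qinit <- c(init$u[1], init$u[2],
               log(max(ax$sigma_major, config$width_bounds[1])),
               log(max(ax$sigma_minor, config$width_bounds[1])),
               ax$theta * pi / 180)
  }
  radius_cap <- max(1L, as.integer(ceiling(4 * config$width_bounds[2])))
  res <- cpp_solve_pixel(frames$sample, frames$reference,
                         as.integer(r0[1]) - 1L, as.integer(r0[2]) - 1L,
                         w$weights, qinit, config$max_shift,
                         config$width_bounds[1], config$width_bounds[2],
                         config$cost_tol, config$param_tol, config$max_eval,
                         KCUT_SOLVER, radius_cap,
                         pmax(config$grid_widths, 1e-3), TRUE)
  structure(list(transmittance = res$T, u = c(res$ux, res$uy),
                 params = blur_kernel(res$a1, res$a2, res$a3),
                 residual = res$cost, converged = res$converged == 1,
                 n_eval = res$nev),
            class = "ddf_pixel_solution")
}

#' @export
print.ddf_pixel_solution <- function(x, ...) {
  ax <- alpha_to_axes(x$params)
  cat(sprintf(paste0("pixel solution: T = %.4f, u = (%.3f, %.3f) px, ",
                     "sigma = (%.3f, %.3f) px, theta = %.2f deg\n"),
              x$transmittance, x$u[1], x$u[2], ax$sigma_major,
              ax$sigma_minor, ax$theta))
  cat(sprintf("  residual = %.6g, converged = %s (%d evaluations)\n",
              x$residual, x$converged, x$n_eval))
  invisible(x)
}

#' Solve one resolution level over the whole image
#'
#' Runs the per-pixel solver independently at every pixel of the stride grid
#' outside the margin.  Deterministic; the result is invariant under the
#' processing order.
#'
#' @inheritParams solve_pixel
#' @param init_maps optional initial parameter maps (a `ddf_signal_maps`
#'   object or a list of full-size matrices `ux, uy, a1, a2, a3`); when
#'   `NULL`, every pixel is initialised by exhaustive grid search.
#' @param step stride of the solve grid (default `config$step`).
#' @return A `ddf_signal_maps` object (see [multires_solve()]).
#' @export
solve_level <- function(frames, config = solver_config(), init_maps = NULL,
                        step = NULL) {
  stopifnot(inherits(frames, "ddf_frames"), inherits(config, "ddf_config"))
  w <- config$window
  d <- dim(frames$sample)
  if (w$size >= min(d[1], d[2]))
    stop("window (", w$size, ") larger than the image (",
         d[1], "x", d[2], ")")
  margin <- solver_margin(w$size, config$max_shift, config$width_bounds[2])
  if (2 * margin >= min(d[1], d[2]))
    stop("margin (", margin, " px) leaves no solvable pixels in a ",
         d[1], "x", d[2], " image")
  if (is.null(step)) step <- config$step
  empty <- matrix(numeric(0), 0, 0)
  if (!is.null(init_maps)) {
    im <- init_maps
    iux <- im$ux; iuy <- im$uy; ia1 <- im$a1; ia2 <- im$a2; ia3 <- im$a3
    stopifnot(identical(dim(iux), d[1:2]))
  } else {
    iux <- iuy <- ia1 <- ia2 <- ia3 <- empty
  }
  radius_cap <- max(1L, as.integer(ceiling(4 * config$width_bounds[2])))
  res <- cpp_solve_level(frames$sample, frames$reference, w$weights,
                         margin, as.integer(step), iux, iuy, ia1, ia2, ia3,
                         config$max_shift, config$width_bounds[1],
                         config$width_bounds[2], config$cost_tol,
                         config$param_tol, config$max_eval, KCUT_SOLVER,
                         radius_cap, pmax(config$grid_widths, 1e-3))
  signal_maps(res, margin = margin, config = config)
}

signal_maps <- function(res, margin, config) {
  structure(list(T = res$T, ux = res$ux, uy = res$uy,
                 a1 = res$a1, a2 = res$a2, a3 = res$a3,
                 residual = res$residual,
                 converged = res$converged,
                 mask = res$mask == 1, margin = margin, config = config),
            class = "ddf_signal_maps")
}

#' @export
print.ddf_signal_maps <- function(x, ...) {
  cat(sprintf("signal maps: %d x %d px, %d solved (margin %d px)\n",
              nrow(x$T), ncol(x$T), sum(x$mask), x$margin))
  invisible(x)
}

bin_frames <- function(frames, b) {
  if (b == 1) return(frames)
  bin_stack <- function(a) {
    s <- lapply(seq_len(dim(a)[3]), function(j) cpp_bin2(a[, , j], b))
    array(unlist(s), dim = c(dim(s[[1]]), length(s)))
  }
  speckle_frame_set(bin_stack(frames$sample), bin_stack(frames$reference),
                    frames$geometry)
}

# pixel-centre coordinates (in full-resolution pixels) of binned pixel i
bin_centres <- function(n, b) (seq_len(n) - 0.5) * b + 0.5

# bilinear interpolation of a matrix sampled at (src_r, src_c) coordinates
# onto (dst_r, dst_c); clamped extrapolation at the edges
interp_grid <- function(M, src_r, src_c, dst_r, dst_c) {
  tmp <- apply(M, 2, function(col)
    stats::approx(src_r, col, xout = dst_r, rule = 2)$y)
  tmp <- matrix(tmp, nrow = length(dst_r))
  out <- t(apply(tmp, 1, function(row)
    stats::approx(src_c, row, xout = dst_c, rule = 2)$y))
  matrix(out, nrow = length(dst_r))
}

# build dense init maps at level b_next from a solved coarser level
upsample_init <- function(maps, b_prev, b_next, dim_next) {
  mk <- maps$mask
  rows <- which(apply(mk, 1, any))
  cols <- which(apply(mk, 2, any))
  ratio <- b_prev / b_next
  src_r <- bin_centres(nrow(mk), b_prev)[rows]
  src_c <- bin_centres(ncol(mk), b_prev)[cols]
  dst_r <- bin_centres(dim_next[1], b_next)
  dst_c <- bin_centres(dim_next[2], b_next)
  up <- function(M) interp_grid(M[rows, cols, drop = FALSE],
                                src_r, src_c, dst_r, dst_c)
  # interpolate the kernel in covariance space (PD-preserving), then invert
  det <- maps$a1 * maps$a3 - maps$a2^2
  cxx <- up(maps$a3 / det) * ratio^2
  cxy <- up(-maps$a2 / det) * ratio^2
  cyy <- up(maps$a1 / det) * ratio^2
  cdet <- pmax(cxx * cyy - cxy^2, 1e-12)
  list(ux = up(maps$ux) * ratio, uy = up(maps$uy) * ratio,
       a1 = cyy / cdet, a2 = -cxy / cdet, a3 = cxx / cdet)
}

# per-level view of the configuration
level_config <- function(config, b) {
  w0 <- config$window$size
  wb <- as.integer(ceiling(w0 / b))
  if (wb %% 2 == 0) wb <- wb + 1L
  wb <- max(wb, 3L)
  cfg <- config
  cfg$window <- hamming_window(wb)
  cfg$max_shift <- max(1, config$max_shift / b)
  cfg$width_bounds <- c(config$width_bounds[1],
                        max(0.3, config$width_bounds[2] / b))
  cfg$step <- max(1L, as.integer(round(config$step / b)))
  cfg
}

#' Multi-resolution retrieval
#'
#' Solves the retrieval on a cascade of binned copies of the data, coarse to
#' fine.  The coarsest level is initialised by exhaustive grid search; each
#' finer level starts from the upsampled previous solution with shifts and
#' widths rescaled by the binning ratio (alpha by the squared ratio).  The
#' final cost at every pixel never exceeds the cost of its upsampled
#' initialisation.
#'
#' @inheritParams solve_level
#' @return A `ddf_signal_maps` object: matrices `T`, `ux`, `uy`, `a1`, `a2`,
#'   `a3`, `residual`, logical `mask` and `converged`, plus the excluded
#'   `margin` and the `config` used.
#' @export
multires_solve <- function(frames, config = solver_config()) {
  stopifnot(inherits(frames, "ddf_frames"), inherits(config, "ddf_config"))
  d <- dim(frames$sample)
  levels <- config$levels
  for (b in levels)
    if (d[1] %% b != 0 || d[2] %% b != 0)
      message("image ", d[1], "x", d[2], " not divisible by level ", b,
              ": edge rows/columns cropped at that level")
  maps <- NULL
  b_prev <- NA_integer_
  for (b in levels) {
    fb <- bin_frames(frames, b)
    cfg <- level_config(config, b)
    init <- NULL
    if (!is.null(maps))
      init <- upsample_init(maps, b_prev, b, dim(fb$sample)[1:2])
    maps <- solve_level(fb, cfg, init_maps = init)
    b_prev <- b
  }
  maps$config <- config
  maps
}
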