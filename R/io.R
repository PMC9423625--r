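# Dataset layout, map output and run-configuration serialisation.

#' Dataset layout
#'
#' Points at the sample and reference stacks on disk.  Sources may be
#' multi-page TIFF files (one page per diffuser position), vectors of
#' single-page TIFF files, or an `.rds` bundle written by [write_dataset()].
#'
#' @param sample,reference source paths.
#' @param geometry a [geometry_spec()].
#' @param dark,flat optional dark/flat frames (matrices or TIFF paths);
#'   `dark` is subtracted from every frame, `flat` divides the result.
#' @return An object of class `ddf_layout`.
#' @export
dataset_layout <- function(sample, reference, geometry = geometry_spec(),
                           dark = NULL, flat = NULL) {
  structure(list(sample = sample, reference = reference, geometry = geometry,
                 dark = dark, flat = flat), class = "ddf_layout")
}

read_stack <- function(src, what) {
  if (is.character(src)) {
    pages <- list()
    for (f in src) {
      if (!file.exists(f)) stop(what, " source not found: ", f)
      if (grepl("\\.rds$", f, ignore.case = TRUE))
        stop("rds bundles are read as a whole dataset, not per stack")
      p <- read_tiff(f)
      if (is.matrix(p)) p <- list(p)
      pages <- c(pages, p)
    }
  } else if (is.array(src) && length(dim(src)) == 3) {
    pages <- lapply(seq_len(dim(src)[3]), function(j) src[, , j])
  } else if (is.matrix(src)) {
    pages <- list(src)
  } else stop("unsupported ", what, " source")
  d1 <- dim(pages[[1]])
  for (j in seq_along(pages))
    if (!identical(dim(pages[[j]]), d1))
      stop(what, " frame ", j, " has shape ",
           paste(dim(pages[[j]]), collapse = "x"), ", expected ",
           paste(d1, collapse = "x"))
  array(unlist(pages), dim = c(d1, length(pages)))
}

#' Read a dataset into a speckle frame set
#'
#' @param layout a [dataset_layout()], or a path to an `.rds` bundle written
#'   by [write_dataset()].
#' @return A [speckle_frame_set()].
#' @export
read_dataset <- function(layout) {
  if (is.character(layout) && length(layout) == 1 &&
      grepl("\\.rds$", layout, ignore.case = TRUE)) {
    b <- readRDS(layout)
    return(speckle_frame_set(b$sample, b$reference,
                             geometry_spec(b$pixel_size, b$distance_d)))
  }
  stopifnot(inherits(layout, "ddf_layout"))
  sample <- read_stack(layout$sample, "sample")
  reference <- read_stack(layout$reference, "reference")
  if (!identical(dim(sample), dim(reference))) {
    if (!identical(dim(sample)[1:2], dim(reference)[1:2]))
      stop("sample frames are ", paste(dim(sample)[1:2], collapse = "x"),
           " but reference frames are ",
           paste(dim(reference)[1:2], collapse = "x"))
    stop("sample has N = ", dim(sample)[3], " frames but reference has N = ",
         dim(reference)[3], "; stacks are not broadcast")
  }
  fix <- function(a) {
    if (!is.null(layout$dark)) {
      d <- if (is.character(layout$dark)) read_tiff(layout$dark)
           else layout$dark
      a <- sweep(a, 1:2, d, `-`)
    }
    if (!is.null(layout$flat)) {
      f <- if (is.character(layout$flat)) read_tiff(layout$flat)
           else layout$flat
      a <- sweep(a, 1:2, f, `/`)
    }
    a[a < 0] <- 0
    a
  }
  speckle_frame_set(fix(sample), fix(reference), layout$geometry)
}

#' Write a synthetic dataset to disk
#'
#' Writes the frame stacks as multi-page float32 TIFFs plus an `.rds` bundle
#' holding frames, geometry, ground truth and provenance.
#'
#' @param ds result of [synthesize_dataset()].
#' @param prefix output path prefix; creates `<prefix>_sample.tif`,
#'   `<prefix>_reference.tif`, `<prefix>.rds` and, when ground truth is
#'   present, `<prefix>_truth_<name>.tif` maps.
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  files <- c(sample = paste0(prefix, "_sample.tif"),
             reference = paste0(prefix, "_reference.tif"),
             bundle = paste0(prefix, ".rds"))
  write_tiff(ds$frames$sample, files[["sample"]])
  write_tiff(ds$frames$reference, files[["reference"]])
  g <- ds$frames$geometry
  saveRDS(list(sample = ds$frames$sample, reference = ds$frames$reference,
               pixel_size = g$pixel_size, distance_d = g$distance_d,
               truth = ds$truth, offsets = ds$offsets), files[["bundle"]])
  if (!is.null(ds$truth)) {
    for (nm in c("T", "ux", "uy", "sigma", "eccentricity", "theta")) {
      f <- paste0(prefix, "_truth_", nm, ".tif")
      write_tiff(ds$truth[[nm]], f)
      files[[paste0("truth_", nm)]] <- f
    }
  }
  invisible(files)
}

#' Write signal and dark-field maps
#'
#' Writes one 32-bit float TIFF per map (`T`, `ux`, `uy`, `sigma`,
#' `eccentricity`, `theta_deg`, `residual`) plus an 8-bit 0/1 `mask`, and an
#' `.rds` bundle holding all maps with the run configuration and seed
#' (canonical archive; an HDF5 writer is intentionally not bundled).
#' Masked-out pixels are written as 0 in the TIFFs.
#'
#' @param maps a `ddf_signal_maps` object from [multires_solve()].
#' @param dir output directory (created if missing).
#' @param config optional run configuration stored with the bundle (defaults
#'   to `maps$config`).
#' @return Named character vector of files written, invisibly.
#' @export
write_maps <- function(maps, dir, config = NULL) {
  stopifnot(inherits(maps, "ddf_signal_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(config)) config <- maps$config
  df <- darkfield_summary(maps)
  out <- list(T = maps$T, ux = maps$ux, uy = maps$uy, sigma = df$sigma,
              eccentricity = df$eccentricity, theta_deg = df$theta,
              residual = maps$residual)
  files <- character(0)
  zero <- function(m) { m[!maps$mask | !is.finite(m)] <- 0; m }
  for (nm in names(out)) {
    f <- file.path(dir, paste0(nm, ".tif"))
    write_tiff(zero(out[[nm]]), f)
    files[nm] <- f
  }
  f <- file.path(dir, "mask.tif")
  write_tiff(matrix(as.integer(maps$mask), nrow(maps$mask)), f,
             type = "uint8")
  files["mask"] <- f
  bundle <- file.path(dir, "maps.rds")
  saveRDS(list(maps = maps, darkfield = df,
               config_json = serialize_config(config),
               seed = config$seed), bundle)
  files["bundle"] <- bundle
  invisible(files)
}

#' Serialise / restore a solver configuration
#'
#' Round-trip-stable JSON representation of a [solver_config()].
#'
#' @param config a [solver_config()].
#' @return `serialize_config`: a JSON string; `deserialize_config`: the
#'   restored `ddf_config`.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "ddf_config"))
  jsonlite::toJSON(list(
    window_size = config$window$size, levels = config$levels,
    max_shift = config$max_shift, width_bounds = config$width_bounds,
    step = config$step, cost_tol = config$cost_tol,
    param_tol = config$param_tol,
    max_eval = config$max_eval, grid_widths = config$grid_widths,
    seed = config$seed), digits = NA, auto_unbox = TRUE)
}

#' @rdname serialize_config
#' @param json a JSON string from `serialize_config`.
#' @export
deserialize_config <- function(json) {
  x <- jsonlite::fromJSON(json)
  solver_config(window = x$window_size, levels = x$levels,
                max_shift = x$max_shift, width_bounds = x$width_bounds,
                step = x$step, cost_tol = x$cost_tol,
                param_tol = x$param_tol,
                max_eval = x$max_eval, grid_widths = x$grid_widths,
                seed = x$seed)
}
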