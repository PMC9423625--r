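# Minimal baseline TIFF I/O (uncompressed, single strip per page).
# No TIFF package ships with the supported environment, and the maps only
# need plain float32/uint8/uint16 grey or uint8 RGB, so a small reader/writer
# is bundled rather than depending on an external library.

TIFF_TYPE_BYTES <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8,
                     `6` = 1, `7` = 1, `8` = 2, `9` = 4, `10` = 8,
                     `11` = 4, `12` = 8)

#' Write images to a TIFF file
#'
#' Writes one page per image: uncompressed, little-endian, single strip.
#' Grey images are matrices; an `[H, W, 3]` array in `[0, 1]` is written as
#' 8-bit RGB.
#'
#' @param images a matrix, an `[H, W, 3]` RGB array, or a list of such (one
#'   page each); a `[H, W, N]` array is treated as N grey pages.
#' @param path output file.
#' @param type sample type for grey pages: `"float32"` (default), `"uint16"`
#'   or `"uint8"`.
#' @return The path, invisibly.
#' @export
write_tiff <- function(images, path, type = c("float32", "uint16", "uint8")) {
  type <- match.arg(type)
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3) {
    if (dim(images)[3] == 3 && max(images, na.rm = TRUE) <= 1 &&
        type == "uint8") {
      images <- list(images)
    } else {
      images <- lapply(seq_len(dim(images)[3]),
                       function(j) images[, , j])
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  # header IFD pointer filled in after layout is known
  offsets <- tiff_layout(images, type)
  writeBin(as.integer(offsets$ifd[1]), con, size = 4, endian = "little")
  for (p in seq_along(images))
    tiff_write_page(con, images[[p]], type, offsets, p,
                    last = p == length(images))
  invisible(path)
}

tiff_page_geom <- function(img, type) {
  rgb <- length(dim(img)) == 3
  H <- dim(img)[1]; W <- dim(img)[2]
  spp <- if (rgb) 3L else 1L
  bps <- if (rgb) 1L else switch(type, float32 = 4L, uint16 = 2L, uint8 = 1L)
  list(H = H, W = W, spp = spp, bytes_per_sample = bps,
       data_bytes = H * W * spp * bps, rgb = rgb)
}

N_TAGS <- 10L

tiff_layout <- function(images, type) {
  # per page: [extra values block][pixel data][IFD]
  pos <- 8
  ifd <- integer(length(images)); data <- integer(length(images))
  extra <- integer(length(images))
  for (p in seq_along(images)) {
    g <- tiff_page_geom(images[[p]], type)
    extra[p] <- pos
    nx <- if (g$spp == 3) 12 else 0  # bits-per-sample + sample-format arrays
    data[p] <- pos + nx
    ifd[p] <- data[p] + g$data_bytes
    if (ifd[p] %% 2 == 1) ifd[p] <- ifd[p] + 1
    pos <- ifd[p] + 2 + N_TAGS * 12 + 4
  }
  list(ifd = ifd, data = data, extra = extra)
}

tiff_write_page <- function(con, img, type, offsets, p, last) {
  g <- tiff_page_geom(img, type)
  fmt <- if (g$rgb) 1L else switch(type, float32 = 3L, uint16 = 1L,
                                   uint8 = 1L)
  # extra arrays for RGB (3 shorts each for tags 258 and 339)
  if (g$spp == 3) {
    writeBin(rep(8L, 3), con, size = 2, endian = "little")
    writeBin(rep(1L, 3), con, size = 2, endian = "little")
  }
  # pixel data, row-major
  if (g$rgb) {
    v <- aperm(img, c(3, 2, 1))  # interleave samples, then columns, rows
    writeBin(as.integer(pmin(pmax(round(v * 255), 0), 255)), con, size = 1)
  } else {
    v <- as.vector(t(img))
    if (type == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(v)), con, size = g$bytes_per_sample,
               endian = "little")
    }
  }
  if ((offsets$data[p] + g$data_bytes) %% 2 == 1)
    writeBin(as.raw(0), con)
  # IFD
  tag <- function(id, typ, n, val) c(id = id, typ = typ, n = n, val = val)
  bits <- g$bytes_per_sample * 8L
  tags <- list(
    tag(256L, 3L, 1L, g$W),
    tag(257L, 3L, 1L, g$H),
    if (g$spp == 3) tag(258L, 3L, 3L, offsets$extra[p])
    else tag(258L, 3L, 1L, bits),
    tag(259L, 3L, 1L, 1L),                       # no compression
    tag(262L, 3L, 1L, if (g$rgb) 2L else 1L),    # photometric
    tag(273L, 4L, 1L, offsets$data[p]),          # strip offset
    tag(277L, 3L, 1L, g$spp),
    tag(278L, 3L, 1L, g$H),                      # rows per strip
    tag(279L, 4L, 1L, g$data_bytes),
    if (g$spp == 3) tag(339L, 3L, 3L, offsets$extra[p] + 6L)
    else tag(339L, 3L, 1L, fmt))
  writeBin(length(tags), con, size = 2, endian = "little")
  for (t in tags) {
    writeBin(as.integer(t[["id"]]), con, size = 2, endian = "little")
    writeBin(as.integer(t[["typ"]]), con, size = 2, endian = "little")
    writeBin(as.integer(t[["n"]]), con, size = 4, endian = "little")
    if (t[["typ"]] == 3L && t[["n"]] == 1L) {
      writeBin(as.integer(t[["val"]]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(t[["val"]]), con, size = 4, endian = "little")
    }
  }
  next_ifd <- if (last) 0L else offsets$ifd[p + 1]
  writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
}

#' Read a TIFF file
#'
#' Reads the uncompressed grey/RGB TIFFs produced by [write_tiff()] (and
#' equivalent baseline files from other tools), both endians.
#'
#' @param path file to read.
#' @return A matrix (single grey page), an `[H, W, 3]` array in `[0, 1]`
#'   (RGB page), or a list of pages.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path)
  rint <- function(at, size, n = 1)
    readBin(raw[(at + 1):(at + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4)
  if (rint(2, 2) != 42L) stop("not a TIFF file: ", path)
  ifd <- rint(4, 4)
  pages <- list()
  while (ifd != 0) {
    nt <- rint(ifd, 2)
    tags <- list()
    for (i in seq_len(nt)) {
      at <- ifd + 2 + (i - 1) * 12
      id <- rint(at, 2); typ <- rint(at + 2, 2); n <- rint(at + 4, 4)
      tb <- TIFF_TYPE_BYTES[[as.character(typ)]]
      vat <- if (tb * n <= 4) at + 8 else rint(at + 8, 4)
      val <- if (typ %in% c(3L, 1L)) rint(vat, tb, n)
             else if (typ == 4L) rint(vat, 4, n)
             else rint(at + 8, 4, 1)
      tags[[as.character(id)]] <- val
    }
    gt <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    W <- gt(256); H <- gt(257)
    bits <- gt(258, 1L); spp <- gt(277, 1L)
    comp <- gt(259, 1L); fmt <- gt(339, 1L)
    if (comp != 1L) stop("compressed TIFF not supported: ", path)
    so <- gt(273); sbc <- gt(279)
    nbytes <- bits[1] %/% 8
    vals <- numeric(0)
    for (s in seq_along(so)) {
      seg <- raw[(so[s] + 1):(so[s] + sbc[s])]
      v <- if (fmt[1] == 3L)
        readBin(seg, "numeric", n = sbc[s] %/% 4, size = 4, endian = endian)
      else if (nbytes == 4)
        readBin(seg, "integer", n = sbc[s] %/% 4, size = 4, endian = endian)
      else {
        x <- readBin(seg, "integer", n = sbc[s] %/% nbytes, size = nbytes,
                     endian = endian, signed = FALSE)
        x
      }
      vals <- c(vals, v)
    }
    page <- if (spp == 3L) {
      a <- array(vals / 255, dim = c(3, W, H))
      aperm(a, c(3, 2, 1))
    } else {
      matrix(vals, nrow = H, ncol = W, byrow = TRUE)
    }
    pages[[length(pages) + 1]] <- page
    ifd <- rint(ifd + 2 + nt * 12, 4)
  }
  if (length(pages) == 1) pages[[1]] else pages
}
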