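## Minimal baseline TIFF: uncompressed grayscale strips, little-endian
## writer, little/big-endian reader, ImageJ-style voxel metadata. Written
## in-package because the runtime provides no R TIFF bindings; validated
## in the test suite against an external reference reader.

TIFF_TYPES <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L,
                SBYTE = 6L, UNDEF = 7L, SSHORT = 8L, SLONG = 9L,
                SRATIONAL = 10L, FLOAT = 11L, DOUBLE = 12L)
TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
raw_u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- x %/% 65536
  as.raw(c(lo %% 256, lo %/% 256, hi %% 256, hi %/% 256))
}

ifd_entry <- function(tag, type, count, value_raw4) {
  c(raw_u16(tag), raw_u16(type), raw_u32(count), value_raw4)
}

#' Write a 3D or 4D grayscale volume as a multi-page TIFF
#'
#' Pages are ordered z-fastest then t (ImageJ hyperstack order for a single
#' channel). Voxel sizes are stored in the X/Y resolution tags (pixels per
#' micrometre) and an ImageJ-style description carrying `spacing` (z step,
#' um), `unit=micron`, and for time-lapse data `finterval` in seconds.
#'
#' @param volume an [image_volume()], [label_volume()], or plain 3D array
#'   (then `voxel_size` is required).
#' @param path output file.
#' @param dtype `"uint8"`, `"uint16"` or `"float32"`; default picks uint16
#'   for non-negative integer-valued data and float32 otherwise.
#' @param voxel_size override / required for bare arrays, `(z,y,x)` um.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(volume, path, dtype = NULL, voxel_size = NULL) {
  frame_interval <- NULL
  if (inherits(volume, "label_volume")) {
    arr <- volume$labels
    voxel_size <- voxel_size %||% volume$voxel_size
    dtype <- dtype %||% "uint16"
  } else if (inherits(volume, "image_volume")) {
    arr <- volume$data
    voxel_size <- voxel_size %||% volume$voxel_size
    frame_interval <- volume$frame_interval
  } else {
    arr <- volume
    if (is.null(voxel_size))
      stop("writing a bare array requires 'voxel_size'")
  }
  nd <- length(dim(arr))
  if (nd == 3L) {
    nt <- 1L; nz <- dim(arr)[1]; ny <- dim(arr)[2]; nx <- dim(arr)[3]
    pages <- lapply(seq_len(nz), function(z) arr[z, , , drop = TRUE])
  } else if (nd == 4L) {
    nt <- dim(arr)[1]; nz <- dim(arr)[2]; ny <- dim(arr)[3]; nx <- dim(arr)[4]
    pages <- vector("list", nt * nz)
    k <- 1L
    for (t in seq_len(nt)) for (z in seq_len(nz)) {
      pages[[k]] <- arr[t, z, , , drop = TRUE]; k <- k + 1L
    }
  } else stop("array must be 3D or 4D")

  if (is.null(dtype)) {
    v <- as.vector(arr)
    intish <- all(v >= 0) && all(v == round(v)) && max(v) <= 65535
    dtype <- if (intish) "uint16" else "float32"
  }
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L,
                 stop("unsupported dtype: ", dtype))
  sampfmt <- if (dtype == "float32") 3L else 1L
  bytespp <- bits / 8L

  desc <- c(sprintf("ImageJ=1.11a"), sprintf("images=%d", length(pages)),
            sprintf("slices=%d", nz))
  if (nt > 1L) desc <- c(desc, sprintf("frames=%d", nt), "hyperstack=true")
  desc <- c(desc, sprintf("spacing=%.6g", voxel_size[1]), "unit=micron",
            "loop=false")
  if (!is.null(frame_interval))
    desc <- c(desc, sprintf("finterval=%.6g", frame_interval * 60))
  desc_raw <- c(charToRaw(paste0(paste(desc, collapse = "\n"), "\n")),
                as.raw(0L))

  res_rational <- function(um_per_px) {
    # pixels per micron as a rational: 1e6 / (um_per_px * 1e6)
    c(raw_u32(1e6), raw_u32(round(um_per_px * 1e6)))
  }
  xres <- res_rational(voxel_size[3])
  yres <- res_rational(voxel_size[2])

  strip_bytes <- ny * nx * bytespp
  n_entries_first <- 14L
  n_entries_rest <- 13L
  ifd_size <- function(n) 2L + n * 12L + 4L

  # layout: header | page1 IFD | desc | xres | yres | strip1 |
  #         page2 IFD | strip2 | ...
  offs <- 8L
  page_meta <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    n_ent <- if (i == 1L) n_entries_first else n_entries_rest
    ifd_off <- offs
    offs <- offs + ifd_size(n_ent)
    desc_off <- xres_off <- yres_off <- NA_integer_
    if (i == 1L) {
      desc_off <- offs; offs <- offs + length(desc_raw)
      if (length(desc_raw) %% 2L) offs <- offs + 1L
      xres_off <- offs; offs <- offs + 8L
      yres_off <- offs; offs <- offs + 8L
    }
    strip_off <- offs
    offs <- offs + strip_bytes
    if (offs %% 2L) offs <- offs + 1L
    page_meta[[i]] <- list(ifd = ifd_off, desc = desc_off, xres = xres_off,
                           yres = yres_off, strip = strip_off, n_ent = n_ent)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), raw_u16(42L), raw_u32(page_meta[[1]]$ifd)), con)
  pos <- 8L

  pad_to <- function(target) {
    if (target > pos) writeBin(raw(target - pos), con)
    pos <<- target
  }

  for (i in seq_along(pages)) {
    m <- page_meta[[i]]
    pad_to(m$ifd)
    sv <- function(x) c(raw_u16(x), raw(2))  # SHORT packed in 4 bytes
    ent <- list(
      ifd_entry(256L, TIFF_TYPES["SHORT"], 1L, sv(nx)),
      ifd_entry(257L, TIFF_TYPES["SHORT"], 1L, sv(ny)),
      ifd_entry(258L, TIFF_TYPES["SHORT"], 1L, sv(bits)),
      ifd_entry(259L, TIFF_TYPES["SHORT"], 1L, sv(1L)),
      ifd_entry(262L, TIFF_TYPES["SHORT"], 1L, sv(1L)))
    if (i == 1L)
      ent <- c(ent, list(ifd_entry(270L, TIFF_TYPES["ASCII"],
                                   length(desc_raw), raw_u32(m$desc))))
    ent <- c(ent, list(
      ifd_entry(273L, TIFF_TYPES["LONG"], 1L, raw_u32(m$strip)),
      ifd_entry(277L, TIFF_TYPES["SHORT"], 1L, sv(1L)),
      ifd_entry(278L, TIFF_TYPES["SHORT"], 1L, sv(ny)),
      ifd_entry(279L, TIFF_TYPES["LONG"], 1L, raw_u32(strip_bytes)),
      ifd_entry(282L, TIFF_TYPES["RATIONAL"], 1L,
                raw_u32(page_meta[[1]]$xres)),
      ifd_entry(283L, TIFF_TYPES["RATIONAL"], 1L,
                raw_u32(page_meta[[1]]$yres)),
      ifd_entry(296L, TIFF_TYPES["SHORT"], 1L, sv(1L)),
      ifd_entry(339L, TIFF_TYPES["SHORT"], 1L, sv(sampfmt))))
    stopifnot(length(ent) == m$n_ent)
    next_ifd <- if (i < length(pages)) page_meta[[i + 1L]]$ifd else 0L
    writeBin(c(raw_u16(length(ent)), unlist(ent), raw_u32(next_ifd)), con)
    pos <- pos + ifd_size(m$n_ent)
    if (i == 1L) {
      pad_to(m$desc); writeBin(desc_raw, con); pos <- pos + length(desc_raw)
      pad_to(m$xres); writeBin(xres, con); pos <- pos + 8L
      pad_to(m$yres); writeBin(yres, con); pos <- pos + 8L
    }
    pad_to(m$strip)
    rowmaj <- as.vector(t(pages[[i]]))  # TIFF rows are x-fastest
    if (dtype == "float32")
      writeBin(as.numeric(rowmaj), con, size = 4, endian = "little")
    else
      writeBin(as.integer(round(rowmaj)), con,
               size = bytespp, endian = "little")
    pos <- pos + strip_bytes
  }
  invisible(path)
}

read_uint <- function(r, size, endian) {
  n <- length(r) / size
  if (size == 2L) {
    v <- readBin(r, "integer", n = n, size = 2, signed = FALSE,
                 endian = endian)
  } else {
    v <- readBin(r, "integer", n = n, size = 4, endian = endian)
    v <- ifelse(v < 0, v + 4294967296, v)
  }
  v
}

#' Read a multi-page grayscale TIFF as an image volume
#'
#' Understands baseline uncompressed TIFF (both byte orders), multiple
#' strips per page, 8/16-bit unsigned and 32-bit float samples, and the
#' ImageJ description convention for z spacing, frame count and frame
#' interval. Axis order is normalized to `(t,)z,y,x`.
#'
#' @param path TIFF file.
#' @param voxel_size optional `(z,y,x)` um override; wins over metadata.
#'   Without metadata or override the reader errors — it never assumes 1 um.
#' @param frame_interval optional override, minutes.
#' @return an [image_volume()].
#' @export
read_tiff <- function(path, voxel_size = NULL, frame_interval = NULL) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stop("not a TIFF file: ", path)
  endian <- if (rawToChar(raw_all[1:2]) == "II") "little"
            else if (rawToChar(raw_all[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path)
  u16 <- function(off, n = 1L)
    read_uint(raw_all[off + seq_len(2L * n)], 2L, endian)
  u32 <- function(off, n = 1L)
    read_uint(raw_all[off + seq_len(4L * n)], 4L, endian)
  if (u16(2L) != 42L) stop("not a TIFF file: ", path)

  read_tag_values <- function(entry_off) {
    tag <- u16(entry_off); type <- u16(entry_off + 2L)
    count <- u32(entry_off + 4L)
    tsz <- TIFF_TYPE_SIZE[type]
    nbytes <- tsz * count
    data_off <- if (nbytes <= 4L) entry_off + 8L else u32(entry_off + 8L)
    bytes <- raw_all[data_off + seq_len(nbytes)]
    vals <- switch(as.character(type),
      "2" = rawToChar(bytes[bytes != as.raw(0)]),
      "3" = read_uint(bytes, 2L, endian),
      "4" = read_uint(bytes, 4L, endian),
      "5" = {
        v <- read_uint(bytes, 4L, endian)
        v[seq(1, length(v), 2)] / pmax(1, v[seq(2, length(v), 2)])
      },
      "1" = as.integer(bytes),
      stop("unsupported TIFF tag type ", type, " for tag ", tag))
    list(tag = tag, values = vals)
  }

  pages <- list()
  desc <- NULL; xres <- NA_real_; yres <- NA_real_
  ifd_off <- u32(4L)
  page_i <- 0L
  while (ifd_off != 0) {
    page_i <- page_i + 1L
    n_ent <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(n_ent)) {
      tv <- read_tag_values(ifd_off + 2L + (e - 1L) * 12L)
      tags[[as.character(tv$tag)]] <- tv$values
    }
    getv <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    if ((getv(259L, 1L))[1] != 1L)
      stop("page ", page_i, ": compressed TIFF not supported")
    nx <- getv(256L)[1]; ny <- getv(257L)[1]
    bits <- getv(258L, 8L)[1]; sampfmt <- getv(339L, 1L)[1]
    spp <- getv(277L, 1L)[1]
    if (spp != 1L) stop("page ", page_i, ": only single-sample TIFF supported")
    offsets <- getv(273L); counts <- getv(279L)
    if (is.null(offsets)) stop("page ", page_i, ": missing strip offsets")
    strip <- unlist(lapply(seq_along(offsets), function(s)
      raw_all[offsets[s] + seq_len(counts[s])]))
    vals <- if (sampfmt == 3L && bits == 32L)
      readBin(strip, "numeric", n = nx * ny, size = 4, endian = endian)
    else if (bits == 8L) as.numeric(as.integer(strip))
    else read_uint(strip, bits / 8L, endian)
    pages[[page_i]] <- matrix(vals, nrow = nx, ncol = ny)  # x-fastest
    if (page_i > 1L &&
        any(dim(pages[[page_i]]) != dim(pages[[1L]])))
      stop("inconsistent page shape at page ", page_i)
    if (page_i == 1L) {
      desc <- getv(270L)
      xres <- (getv(282L, NA_real_))[1]
      yres <- (getv(283L, NA_real_))[1]
    }
    ifd_off <- u32(ifd_off + 2L + n_ent * 12L)
  }

  meta <- list(spacing = NA_real_, frames = 1L, slices = length(pages),
               finterval = NA_real_)
  if (!is.null(desc)) {
    for (ln in strsplit(desc, "\n")[[1]]) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L && kv[1] %in% names(meta))
        meta[[kv[1]]] <- suppressWarnings(as.numeric(kv[2]))
    }
  }
  nt <- as.integer(meta$frames %||% 1L)
  if (is.na(nt) || nt < 1L) nt <- 1L
  nz <- length(pages) / nt
  if (nz != round(nz))
    stop("page count ", length(pages), " not divisible by frames=", nt)
  nz <- as.integer(nz)

  if (is.null(voxel_size)) {
    vx <- if (is.finite(xres) && xres > 0) 1 / xres else NA_real_
    vy <- if (is.finite(yres) && yres > 0) 1 / yres else NA_real_
    vz <- meta$spacing
    voxel_size <- c(vz, vy, vx)
    if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
      stop("no voxel-size metadata in ", path,
           " and no 'voxel_size' override given; refusing to assume 1 um")
  }
  if (is.null(frame_interval) && is.finite(meta$finterval))
    frame_interval <- meta$finterval / 60
  nxl <- dim(pages[[1]])[1]; nyl <- dim(pages[[1]])[2]
  if (nt == 1L) {
    arr <- array(0, dim = c(nz, nyl, nxl))
    for (z in seq_len(nz)) arr[z, , ] <- t(pages[[z]])
    image_volume(arr, voxel_size)
  } else {
    arr <- array(0, dim = c(nt, nz, nyl, nxl))
    k <- 1L
    for (t in seq_len(nt)) for (z in seq_len(nz)) {
      arr[t, z, , ] <- t(pages[[k]]); k <- k + 1L
    }
    image_volume(arr, voxel_size, frame_interval = frame_interval %||% 1)
  }
}

#' Read or write a 16-bit label TIFF as a label volume
#'
#' @inheritParams read_tiff
#' @param provenance recorded provenance of the imported masks.
#' @return [read_labels()] returns a [label_volume()].
#' @export
read_labels <- function(path, voxel_size = NULL,
                        provenance = "manual_import") {
  v <- read_tiff(path, voxel_size = voxel_size)
  label_volume(round(v$data), v$voxel_size, provenance = provenance)
}
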