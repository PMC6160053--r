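#' Voxel volume and binary volume containers
#'
#' A `voxel_volume` holds a 3D grid of 8-bit intensities (0--255) together
#' with its physical voxel size (micrometres per voxel edge, isotropic) and
#' the physical offset of the grid origin. A `binary_volume` holds the
#' corresponding segmentation mask. The centre of voxel `[i, j, k]` (1-based)
#' sits at `origin + (c(i, j, k) - 0.5) * voxel_size`, so image space and
#' graph space share one coordinate convention without half-voxel drift.
#'
#' @param data 3D numeric array of intensities in `[0, 255]`.
#' @param voxel_size Edge length of a voxel in micrometres (must be `> 0`).
#' @param origin Physical position (um) of the corner of voxel `[1, 1, 1]`.
#'
#' @return An object of class `voxel_volume` (or `binary_volume`).
#' @examples
#' v <- voxel_volume(array(100, c(4, 4, 4)), voxel_size = 3)
#' dim(v$data)
#' @export
voxel_volume <- function(data, voxel_size = 3, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array (not a 3D volume otherwise)")
  }
  if (any(dim(data) < 1L)) abort("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    abort("`voxel_size` must be a single positive number (um)")
  }
  storage.mode(data) <- "double"
  if (anyNA(data) || min(data) < 0 || max(data) > 255) {
    abort("intensities must lie within [0, 255]")
  }
  structure(
    list(data = data, voxel_size = voxel_size, origin = as.numeric(origin)),
    class = "voxel_volume"
  )
}

#' @param mask 3D logical array (foreground `TRUE`).
#' @rdname voxel_volume
#' @export
binary_volume <- function(mask, voxel_size = 3, origin = c(0, 0, 0)) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a 3D array")
  }
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) abort("`mask` must be logical or 0/1")
    mask <- array(as.logical(mask), dim(mask))
  }
  if (anyNA(mask)) abort("`mask` must not contain NA")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    abort("`voxel_size` must be a single positive number (um)")
  }
  structure(
    list(mask = mask, voxel_size = voxel_size, origin = as.numeric(origin)),
    class = "binary_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, %.3g um/voxel, intensity [%g, %g]\n",
    d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<binary_volume> %d x %d x %d voxels, %.3g um/voxel, foreground %.1f%%\n",
    d[1], d[2], d[3], x$voxel_size, 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Convert a binary volume to an 8-bit voxel volume
#'
#' Foreground voxels receive a constant intensity (default 124, the middle of
#' the standard 76--172 segmentation band, so that re-thresholding with the
#' default band recovers the mask), background another.
#'
#' @param bin A `binary_volume`.
#' @param fg,bg Intensities assigned to foreground / background voxels.
#' @return A `voxel_volume`.
#' @export
as_voxel_volume <- function(bin, fg = 124, bg = 0) {
  stopifnot(inherits(bin, "binary_volume"))
  dat <- array(bg, dim(bin$mask))
  dat[bin$mask] <- fg
  voxel_volume(dat, voxel_size = bin$voxel_size, origin = bin$origin)
}

# physical coordinates (um) of voxel centres for 1-based index matrix idx
voxel_centers <- function(idx, voxel_size, origin = c(0, 0, 0)) {
  sweep((idx - 0.5) * voxel_size, 2, origin, "+")
}

# ---------------------------------------------------------------------------
# File input / output
# ---------------------------------------------------------------------------

#' Read a 3D micro-CT volume from a TIFF stack or NRRD file
#'
#' Multi-page 8-bit TIFF stacks are read with the tiff package (one page per
#' z slice); NRRD files are parsed directly (raw, ascii/text and gzip
#' encodings). Non-8-bit data are rejected unless `rescale = TRUE`, in which
#' case they are linearly rescaled to `[0, 255]`. Anisotropic NRRD spacing
#' metadata is rejected unless `voxel_size` explicitly overrides it.
#'
#' @param path File path.
#' @param format `"tiff"`, `"nrrd"`, or `NULL` to infer from the extension.
#' @param voxel_size Voxel edge length in um; overrides file metadata.
#'   When neither is available the scanner default of 3 um is used.
#' @param rescale Allow non-8-bit input and rescale it to `[0, 255]`.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = NULL, voxel_size = NULL,
                        rescale = FALSE) {
  if (!file.exists(path)) abort(paste0("cannot read volume: no file at ", path))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      tif = , tiff = "tiff",
      nrrd = , nhdr = "nrrd",
      abort(paste0("cannot infer volume format from extension '", ext, "'"))
    )
  }
  format <- match.arg(format, c("tiff", "nrrd"))
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L || length(dim(pages[[1]])) != 2L) {
      abort("not a 3D volume: TIFF stack must hold >= 2 single-channel pages")
    }
    sample_bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
    mx <- max(vapply(pages, max, 0))
    if ((sample_bits > 8L || mx > 255) && !rescale) {
      abort("non-8-bit TIFF data; pass rescale = TRUE to rescale to [0, 255]")
    }
    # pages are y (rows) by x (cols); store as data[x, y, z]
    nz <- length(pages)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    dat <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) dat[, , k] <- t(pages[[k]])
    if (mx > 255) dat <- dat / mx * 255
    voxel_volume(dat, voxel_size = voxel_size %||% 3)
  } else {
    nr <- read_nrrd(path)
    if (!is.null(nr$spacings) && is.null(voxel_size)) {
      sp <- nr$spacings
      if (diff(range(sp)) > 1e-9 * max(sp)) {
        abort("anisotropic voxel spacing; pass `voxel_size` to override")
      }
      voxel_size <- sp[1]
    }
    if (max(nr$data) > 255 || min(nr$data) < 0) {
      if (!rescale) {
        abort("non-8-bit NRRD data; pass rescale = TRUE to rescale to [0, 255]")
      }
      nr$data <- (nr$data - min(nr$data)) / diff(range(nr$data)) * 255
    }
    voxel_volume(nr$data, voxel_size = voxel_size %||% 3)
  }
}

#' Write a volume to a TIFF stack or NRRD file
#'
#' @param vol A [voxel_volume()] or [binary_volume()] (a mask is written as
#'   0/255 intensities).
#' @param path Output file path.
#' @param format `"tiff"`, `"nrrd"`, or `NULL` to infer from the extension.
#' @param encoding NRRD encoding, `"raw"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL, encoding = "raw") {
  if (inherits(vol, "binary_volume")) vol <- as_voxel_volume(vol, fg = 255)
  stopifnot(inherits(vol, "voxel_volume"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      tif = , tiff = "tiff",
      nrrd = "nrrd",
      abort(paste0("cannot infer volume format from extension '", ext, "'"))
    )
  }
  format <- match.arg(format, c("tiff", "nrrd"))
  if (format == "tiff") {
    d <- dim(vol$data)
    pages <- lapply(seq_len(d[3]), function(k) t(vol$data[, , k]) / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    write_nrrd(vol, path, encoding = encoding)
  }
  invisible(path)
}

# Minimal NRRD reader: header of "key: value" lines, blank line, then data.
# Supports type uint8/uchar/int/float/double, encodings raw / ascii (text) /
# gzip, dimension 3, optional "spacings:" metadata.
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) abort("not an NRRD file (missing NRRD magic)")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) abort("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):[=]? *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  ndim <- as.integer(fields[["dimension"]] %||% "0")
  if (ndim != 3L) abort("not a 3D volume: NRRD dimension must be 3")
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  type <- tolower(fields[["type"]] %||% "uint8")
  enc <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  vals <- switch(enc,
    raw = {
      what <- if (type %in% c("uint8", "uchar", "unsigned char")) "integer"
              else "double"
      size <- switch(type,
        uint8 = , uchar = , `unsigned char` = 1L,
        int = , int32 = , signed_int = 4L,
        float = 4L,
        double = 8L,
        abort(paste0("unsupported NRRD type '", type, "'"))
      )
      readBin(con, what, n = n, size = size,
              signed = !(size == 1L), endian = "little")
    },
    gzip = , gz = {
      raw_rest <- readBin(con, "raw", n = file.info(path)$size)
      dec <- memDecompress(raw_rest, type = "gzip")
      if (type %in% c("uint8", "uchar", "unsigned char")) {
        as.integer(dec)[seq_len(n)]
      } else {
        readBin(dec, "double", n = n, size = 8L, endian = "little")
      }
    },
    ascii = , text = , txt = {
      txt <- readLines(con)
      as.numeric(scan(text = paste(txt, collapse = " "), quiet = TRUE))
    },
    abort(paste0("unsupported NRRD encoding '", enc, "'"))
  )
  if (length(vals) < n) abort("truncated NRRD data block")
  spacings <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacings <- as.numeric(strsplit(fields[["spacings"]], " +")[[1]])
  }
  list(data = array(as.numeric(vals[seq_len(n)]), sizes), spacings = spacings)
}

write_nrrd <- function(vol, path, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  d <- dim(vol$data)
  hdr <- c(
    "NRRD0004",
    "# 8-bit micro-CT volume",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %g %g %g", vol$voxel_size, vol$voxel_size,
            vol$voxel_size),
    "endian: little",
    sprintf("encoding: %s", if (encoding == "raw") "raw" else "text"),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  vals <- as.integer(round(as.vector(vol$data)))
  if (encoding == "raw") {
    writeBin(vals, con, size = 1L)
  } else {
    writeLines(paste(vals, collapse = " "), con)
  }
  invisible(path)
}
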