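# Image format I/O. MRC2014 is read (modes 0/1/2/6) and written (mode 2,
# 32-bit float, little-endian, voxel size set in the header); TIFF goes
# through the tiff package (no spacing metadata; 32-bit storage quantises
# values in [0, 1] at 2^-32); Dynamo EM is read-only. Arrays are [x, y, z]
# (x fastest), the on-disk order of all three formats.

MRC_EXTENSIONS <- c("mrc", "mrcs", "st", "map", "rec")
IMAGE_EXTENSIONS <- c(MRC_EXTENSIONS, "tif", "tiff", "em")

read_mrc_header <- function(con) {
  h <- list()
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  h$nx <- ints[1]; h$ny <- ints[2]; h$nz <- ints[3]; h$mode <- ints[4]
  h$mx <- ints[8]; h$my <- ints[9]; h$mz <- ints[10]
  cella <- readBin(con, "double", n = 3, size = 4, endian = "little")
  h$xlen <- cella[1]
  seek(con, 92)
  h$nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  h
}

#' Read an MRC2014 volume
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16),
#' little-endian. The pixel spacing is `cella_x / mx` from the header (0
#' when the header does not define it).
#'
#' @param path MRC file path.
#' @param header_only Read only the header (dimensions and spacing)?
#' @return An [image_volume()]; with `header_only = TRUE` the volume has no
#'   data but carries `dim` and `pixel_spacing`.
#' @export
read_mrc <- function(path, header_only = FALSE) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  h <- tryCatch(read_mrc_header(con),
                error = function(e) abort_format(
                  sprintf("corrupt MRC header in %s", path)))
  if (any(c(h$nx, h$ny, h$nz) <= 0) || any(c(h$nx, h$ny, h$nz) > 1e5) ||
      !h$mode %in% c(0, 1, 2, 6)) {
    abort_format(sprintf("unsupported or corrupt MRC file %s (mode %s)",
                         path, h$mode))
  }
  spacing <- if (!is.na(h$xlen) && h$mx > 0 && h$xlen > 0) h$xlen / h$mx else 0
  if (header_only) {
    return(image_volume(loader = function() image_data(read_mrc(path)),
                        pixel_spacing = spacing,
                        dim = c(h$nx, h$ny, h$nz)))
  }
  seek(con, 1024 + h$nsymbt)
  nvox <- h$nx * h$ny * h$nz
  raw_data <- switch(as.character(h$mode),
    "0" = readBin(con, "integer", n = nvox, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = nvox, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "double", n = nvox, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = nvox, size = 2, signed = FALSE,
                  endian = "little"))
  if (length(raw_data) < nvox) {
    abort_format(sprintf("truncated MRC data in %s: expected %d voxels, got %d",
                         path, nvox, length(raw_data)))
  }
  data <- array(as.double(raw_data), dim = c(h$nx, h$ny, h$nz))
  image_volume(data, pixel_spacing = spacing)
}

#' Write a volume as MRC2014 (mode 2, 32-bit float)
#'
#' The voxel size header fields are set from the volume's pixel spacing.
#'
#' @param volume An [image_volume()] or numeric 2D/3D array.
#' @param path Output path.
#' @param pixel_spacing Spacing override in Angstrom per voxel; defaults to
#'   the volume's own.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(volume, path, pixel_spacing = NULL) {
  if (!inherits(volume, "image_volume")) volume <- image_volume(volume)
  data <- image_data(volume)
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  spacing <- if (is.null(pixel_spacing)) volume$pixel_spacing else pixel_spacing
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(c(d * spacing, 90, 90, 90), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(c(min(data), max(data), mean(data)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")  # ispg, nsymbt
  writeBin(raw(100), con)                                            # extra
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                   # machst LE
  writeBin(stats::sd(data), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                     # nlabl
  writeBin(raw(800), con)                                            # labels
  writeBin(as.vector(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a Dynamo EM volume
#'
#' Read-only support for the 512-byte-header EM format (int8, int16, int32,
#' float32 and float64 payloads, little-endian).
#'
#' @param path EM file path.
#' @return An [image_volume()] (pixel spacing unknown, 0).
#' @export
read_em <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  head4 <- readBin(con, "integer", n = 4, size = 1, signed = TRUE)
  dtype <- head4[4]
  dims <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  if (any(dims <= 0) || any(dims > 1e5)) {
    abort_format(sprintf("corrupt EM header in %s", path))
  }
  seek(con, 512)
  nvox <- prod(dims)
  raw_data <- switch(as.character(dtype),
    "1" = readBin(con, "integer", n = nvox, size = 1, signed = TRUE),
    "2" = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    "4" = readBin(con, "integer", n = nvox, size = 4, endian = "little"),
    "5" = readBin(con, "double", n = nvox, size = 4, endian = "little"),
    "9" = readBin(con, "double", n = nvox, size = 8, endian = "little"),
    abort_format(sprintf("unsupported EM data type %d", dtype)))
  if (length(raw_data) < nvox) {
    abort_format(sprintf("truncated EM data in %s", path))
  }
  image_volume(array(as.double(raw_data), dim = dims))
}

read_tiff_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse channel axis
    p
  })
  data <- if (length(pages) == 1) pages[[1]] else
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  image_volume(data, pixel_spacing = 0)
}

write_tiff_image <- function(volume, path) {
  if (!inherits(volume, "image_volume")) volume <- image_volume(volume)
  data <- image_data(volume)
  if (length(dim(data)) == 3) {
    pages <- lapply(seq_len(dim(data)[3]), function(k) data[, , k])
  } else {
    pages <- list(data)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(path)
}

#' Read an image volume, dispatching on the file extension
#'
#' `.mrc/.mrcs/.st/.map/.rec` are read as MRC2014, `.tif/.tiff` as
#' (multipage) TIFF, `.em` as Dynamo EM.
#'
#' @param path Image file path.
#' @param lazy Defer reading the voxel data (MRC only): the header is read
#'   eagerly, the array on first [image_data()] access.
#' @return An [image_volume()].
#' @export
read_image <- function(path, lazy = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% MRC_EXTENSIONS) {
    if (lazy) read_mrc(path, header_only = TRUE) else read_mrc(path)
  } else if (ext %in% c("tif", "tiff")) {
    read_tiff_image(path)
  } else if (ext == "em") {
    read_em(path)
  } else {
    abort_format(sprintf(
      "unsupported image extension '%s'; supported: %s", ext,
      paste(IMAGE_EXTENSIONS, collapse = ", ")))
  }
}

#' Write an image volume, dispatching on the file extension
#'
#' @param volume An [image_volume()] or numeric array.
#' @param path Output path ending in `.mrc` (or variant) or `.tif(f)`.
#' @return `path`, invisibly.
#' @export
write_image <- function(volume, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% MRC_EXTENSIONS) {
    write_mrc(volume, path)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff_image(volume, path)
  } else {
    abort_format(sprintf(
      "unsupported output extension '%s'; supported: %s", ext,
      paste(c(MRC_EXTENSIONS, "tif", "tiff"), collapse = ", ")))
  }
}

#' Read an integer label volume from MRC or TIFF
#'
#' Voxel values are rounded to the nearest integer.
#'
#' @param path Image file path.
#' @return A [labeled_volume()].
#' @export
read_labels <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    data <- if (length(pages) == 1) pages[[1]] else
      array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    return(labeled_volume(array(as.integer(round(data)), dim(data))))
  }
  vol <- read_image(path)
  data <- image_data(vol)
  labeled_volume(array(as.integer(round(data)), dim(data)))
}

#' Write an integer label volume to MRC or TIFF
#'
#' MRC labels are stored as mode-2 float (integer-valued); TIFF labels as
#' 16-bit integer pages.
#'
#' @param labels A [labeled_volume()] or integer array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  data <- if (inherits(labels, "labeled_volume")) labels$data else
    labeled_volume(labels)$data
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(data) > 65535L) abort_argument("TIFF labels limited to 16 bits")
    scaled <- data / 65535
    pages <- if (length(dim(data)) == 3) {
      lapply(seq_len(dim(data)[3]), function(k) scaled[, , k])
    } else list(scaled)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    return(invisible(path))
  }
  write_mrc(image_volume(array(as.double(data), dim(data))), path)
}
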