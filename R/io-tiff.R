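#' Calibrated grayscale image
#'
#' A single-plane grayscale raster with its spatial calibration: the size of
#' one pixel in microns. Intensities are stored as raw values in the range
#' of the declared bit depth (0..255 for 8-bit, 0..65535 for 16-bit;
#' 32-bit images are floating point).
#'
#' @param pixels numeric matrix, rows top-down.
#' @param pixel_size microns per pixel (> 0).
#' @param unit length-unit label, default `"micron"`.
#' @param bit_depth 8, 16 or 32.
#' @param source identifier of the originating file, if any.
#' @return object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size, unit = "micron",
                             bit_depth = 8L, source = "") {
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    ms_validation("pixel_size must be a positive scalar (microns per pixel)")
  if (!is.matrix(pixels) || nrow(pixels) < 2L || ncol(pixels) < 2L)
    ms_validation("pixels must be a matrix with at least 2 rows and 2 columns")
  if (!bit_depth %in% c(8L, 16L, 32L))
    ms_validation("bit_depth must be one of 8, 16, 32")
  if (bit_depth < 32L) {
    rng <- range(pixels)
    if (rng[1L] < 0 || rng[2L] > 2^bit_depth - 1)
      ms_validation(sprintf("intensities outside the %d-bit range", bit_depth))
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, unit = unit,
                 bit_depth = as.integer(bit_depth), source = source),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %g %s/px, %d-bit\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$unit, x$bit_depth))
  invisible(x)
}

#' Read a calibrated single-plane grayscale TIFF
#'
#' Pixel data are read with the tiff package; the spatial calibration is
#' recovered from the TIFF tags the ImageJ calibration step writes
#' (XResolution = pixels per unit, unit in the ImageDescription).
#'
#' @param path TIFF file.
#' @param pixel_size override/supply microns per pixel when the file carries
#'   no resolution tag.
#' @return a [calibrated_image()].
#' @export
read_calibrated_tiff <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) ms_io(sprintf("cannot read '%s': no such file", path))
  planes <- try(suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE,
                                                as.is = TRUE)), silent = TRUE)
  if (inherits(planes, "try-error"))
    ms_io(sprintf("cannot decode '%s' as TIFF", path))
  if (length(planes) != 1L)
    ms_format(sprintf("'%s' is a multi-plane TIFF (%d planes); expected a single plane",
                      path, length(planes)))
  px <- planes[[1L]]
  if (length(dim(px)) == 3L)
    ms_format(sprintf("'%s' is an RGB/multi-channel TIFF; expected grayscale", path))
  bits <- attr(px, "bits.per.sample") %||% 8L
  xres <- attr(px, "x.resolution")
  if (is.null(pixel_size)) {
    if (is.null(xres) || xres <= 0)
      ms_validation(sprintf("'%s' carries no pixel-size calibration; supply pixel_size", path))
    pixel_size <- 1 / xres
  }
  unit <- "micron"
  desc <- attr(px, "description")
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("unit=([^\n]+)", desc))[[1L]]
    if (length(m) == 2L) unit <- trimws(m[2L])
  }
  pixels <- matrix(as.numeric(px), nrow(px), ncol(px))
  if (bits < 32L && max(pixels) <= 1 && any(pixels %% 1 != 0)) {
    # reader returned normalized [0,1] values (no as.is support for this
    # sample layout): restore raw units
    pixels <- pixels * (2^bits - 1)
  }
  calibrated_image(pixels, pixel_size, unit = unit, bit_depth = as.integer(bits),
                   source = path)
}

#' Write a calibrated grayscale TIFF
#'
#' Emits an uncompressed single-strip baseline TIFF (little-endian) with the
#' ImageDescription and XResolution/YResolution tags that carry the pixel
#' calibration, so the file round-trips through ImageJ's
#' "Set Scale" convention (resolution = pixels per unit).
#'
#' @param image a [calibrated_image()].
#' @param path destination.
#' @export
write_calibrated_tiff <- function(image, path) {
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  bits <- image$bit_depth
  desc <- sprintf("ImageJ=1.54f\nunit=%s\n", image$unit)
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))

  data_off <- 8L
  nbytes <- H * W * (bits %/% 8L)
  if (nbytes %% 2L) nbytes <- nbytes + 1L
  res_off <- data_off + nbytes           # XResolution RATIONAL (8 bytes), then Y
  desc_off <- res_off + 16L
  ifd_off <- desc_off + length(desc_raw)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  # pixel data, row-major strips
  v <- as.vector(t(px))
  if (bits == 8L) {
    writeBin(as.raw(pmin(pmax(round(v), 0), 255)), con)
  } else if (bits == 16L) {
    iv <- as.integer(pmin(pmax(round(v), 0), 65535))
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L   # reinterpret as signed for writeBin
    writeBin(iv, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  }
  if ((H * W * (bits %/% 8L)) %% 2L) writeBin(as.raw(0L), con)
  # resolution: pixels per unit = 1 / pixel_size, as the RATIONAL
  # 1e7 / (pixel_size * 1e7) so the pixel size survives exactly
  num <- 10000000L
  den <- round(image$pixel_size * 1e7)
  writeBin(as.integer(c(num, den, num, den)), con, size = 4, endian = "little")
  writeBin(desc_raw, con)

  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  tag <- function(id, type, count, value, short = type == 3L) {
    w2(id); w2(type); w4(count)
    if (short) { w2(value); w2(0L) } else w4(value)
  }
  entries <- 13L
  w2(entries)
  tag(256L, 3L, 1L, W)                      # ImageWidth
  tag(257L, 3L, 1L, H)                      # ImageLength
  tag(258L, 3L, 1L, bits)                   # BitsPerSample
  tag(259L, 3L, 1L, 1L)                     # Compression = none
  tag(262L, 3L, 1L, 1L)                     # Photometric = BlackIsZero
  tag(270L, 2L, length(desc_raw), desc_off, short = FALSE)  # ImageDescription
  tag(273L, 4L, 1L, data_off, short = FALSE)                # StripOffsets
  tag(277L, 3L, 1L, 1L)                     # SamplesPerPixel
  tag(278L, 3L, 1L, H)                      # RowsPerStrip
  tag(279L, 4L, 1L, H * W * (bits %/% 8L), short = FALSE)   # StripByteCounts
  tag(282L, 5L, 1L, res_off, short = FALSE)                 # XResolution
  tag(283L, 5L, 1L, res_off + 8L, short = FALSE)            # YResolution
  tag(339L, 3L, 1L, if (bits == 32L) 3L else 1L)            # SampleFormat
  w4(0L)                                    # no next IFD
  invisible(path)
}

#' Calibrate an image file
#'
#' Reads a single-plane grayscale TIFF, attaches the pixel-size calibration
#' and converts to the target bit depth. Narrowing (e.g. 16-bit to 8-bit)
#' uses a linear min-max mapping onto the full target range; an image with
#' zero dynamic range maps to 0. Calibration is idempotent on files already
#' in the target depth. The file is only overwritten when `write = TRUE`;
#' the default leaves raw data untouched and returns the calibrated image.
#'
#' @param path TIFF file.
#' @param pixel_size microns per pixel (> 0).
#' @param unit length-unit label.
#' @param bit_depth target depth: 8, 16 or 32.
#' @param write overwrite `path` with the calibrated image.
#' @return a [calibrated_image()], invisibly when `write = TRUE`.
#' @export
calibrate_image <- function(path, pixel_size, unit = "micron", bit_depth = 8L,
                            write = FALSE) {
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    ms_validation("pixel_size must be a positive scalar")
  img <- read_calibrated_tiff(path, pixel_size = pixel_size)
  px <- img$pixels
  if (bit_depth < img$bit_depth) {
    rng <- range(px)
    top <- 2^bit_depth - 1
    px <- if (rng[2L] > rng[1L]) round((px - rng[1L]) / (rng[2L] - rng[1L]) * top)
          else matrix(0, nrow(px), ncol(px))
  }
  out <- calibrated_image(px, pixel_size, unit = unit,
                          bit_depth = as.integer(bit_depth), source = path)
  if (write) {
    write_calibrated_tiff(out, path)
    return(invisible(out))
  }
  out
}
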