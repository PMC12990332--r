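#' Polygonal region of interest
#'
#' An ImageJ-style polygon ROI: ordered vertices in 0-based pixel
#' coordinates (x right, y down, pixel-centered), implicitly closed.
#'
#' @param vertices two-column numeric matrix (x, y), at least 3 rows.
#' @param name ROI name.
#' @return object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, name = "") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    ms_validation("an ROI polygon needs at least 3 (x, y) vertices")
  d <- rowSums(abs(vertices - vertices[c(2:nrow(vertices), 1L), , drop = FALSE]))
  if (any(d == 0)) vertices <- vertices[d > 0, , drop = FALSE]
  if (nrow(vertices) < 3L)
    ms_validation("ROI degenerates to fewer than 3 distinct vertices")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, name = name), class = "roi_polygon")
}

# ImageJ ROI type codes
.roi_types <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
                polyline = 5L, noroi = 6L, freehand = 7L, traced = 8L,
                angle = 9L, point = 10L)

#' Read an ImageJ .roi file (or a .zip of them)
#'
#' Parses the ImageJ binary ROI format (big-endian, magic "Iout").
#' Polygon, freehand and traced subtypes are supported; when the file
#' carries the sub-pixel-resolution float coordinate block, those exact
#' coordinates are returned.
#'
#' @param x path to a `.roi` or `.zip` file, or a raw vector.
#' @return a [roi_polygon()], or a list of them for a zip archive.
#' @export
read_imagej_roi <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) ms_io(sprintf("cannot read '%s': no such file", x))
    if (grepl("\\.zip$", x, ignore.case = TRUE)) return(read_roi_zip(x))
    raw <- readBin(x, "raw", file.info(x)$size)
    nm <- sub("\\.roi$", "", basename(x), ignore.case = TRUE)
  } else if (is.raw(x)) {
    if (length(x) >= 4L && rawToChar(x[1:2]) == "PK") return(read_roi_zip(x))
    raw <- x
    nm <- ""
  } else ms_validation("x must be a file path or a raw vector")
  parse_roi_blob(raw, default_name = nm)
}

read_roi_zip <- function(x) {
  tmp <- tempfile("roizip")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  if (is.raw(x)) {
    zf <- file.path(tmp, "rois.zip")
    writeBin(x, zf)
    x <- zf
  }
  files <- utils::unzip(x, exdir = tmp)
  files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
  if (!length(files)) ms_format("zip archive contains no .roi entries")
  lapply(files, read_imagej_roi)
}

parse_roi_blob <- function(raw, default_name = "") {
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    ms_format("not an ImageJ ROI: missing 'Iout' magic")
  rd2 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               endian = "big", signed = TRUE)
  rd4 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = "big")
  type <- as.integer(raw[7L])
  if (!type %in% .roi_types[c("polygon", "freehand", "traced")]) {
    nm <- names(.roi_types)[match(type, .roi_types)]
    ms_format(sprintf("unsupported ROI type '%s'; only polygon, freehand and traced ROIs carry a closed outline",
                      if (is.na(nm)) as.character(type) else nm))
  }
  top <- rd2(8L); left <- rd2(10L)
  n <- rd2(16L)
  options <- rd2(50L)
  h2 <- rd4(60L)
  if (n < 3L) ms_format("ROI has fewer than 3 vertices")
  xi <- readBin(raw[65:(64 + 2 * n)], "integer", n = n, size = 2,
                endian = "big", signed = TRUE)
  yi <- readBin(raw[(65 + 2 * n):(64 + 4 * n)], "integer", n = n, size = 2,
                endian = "big", signed = TRUE)
  xs <- left + xi
  ys <- top + yi
  fc_off <- 64L + 4L * n
  if (bitwAnd(options, 128L) && length(raw) >= fc_off + 8L * n) {
    xs <- readBin(raw[(fc_off + 1):(fc_off + 4 * n)], "numeric", n = n,
                  size = 4, endian = "big")
    ys <- readBin(raw[(fc_off + 4 * n + 1):(fc_off + 8 * n)], "numeric", n = n,
                  size = 4, endian = "big")
  }
  nm <- default_name
  if (h2 > 0L && length(raw) >= h2 + 64L) {
    name_off <- rd4(h2 + 16L)
    name_len <- rd4(h2 + 20L)
    if (name_off > 0L && name_len > 0L && length(raw) >= name_off + 2L * name_len) {
      chars <- readBin(raw[(name_off + 1):(name_off + 2 * name_len)], "integer",
                       n = name_len, size = 2, endian = "big", signed = FALSE)
      nm <- intToUtf8(chars)
    }
  }
  roi_polygon(cbind(xs, ys), name = nm)
}

#' Write an ImageJ .roi file
#'
#' Serializes a polygon ROI in the ImageJ binary layout (big-endian), with
#' the sub-pixel-resolution float coordinate block so that
#' `read_imagej_roi(write_imagej_roi(p))` reproduces the vertices exactly.
#'
#' @param polygon a [roi_polygon()].
#' @param path optional destination; when `NULL` the raw blob is returned.
#' @return raw vector (invisibly when written to a file).
#' @export
write_imagej_roi <- function(polygon, path = NULL) {
  if (!inherits(polygon, "roi_polygon"))
    ms_validation("polygon must be an roi_polygon")
  v <- polygon$vertices
  n <- nrow(v)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  left <- floor(min(v[, 1L])); top <- floor(min(v[, 2L]))
  right <- ceiling(max(v[, 1L])); bottom <- ceiling(max(v[, 2L]))
  writeBin(charToRaw("Iout"), con)
  wr2(228L)                                   # version
  writeBin(as.raw(c(.roi_types[["polygon"]], 0L)), con)
  wr2(c(top, left, bottom, right, n))
  writeBin(numeric(4), con, size = 4, endian = "big")   # x1,y1,x2,y2
  wr2(0L); wr4(0L); wr4(0L); wr4(0L)          # stroke width/shape size/colors
  wr2(0L)                                     # subtype
  wr2(128L)                                   # options: sub-pixel resolution
  writeBin(as.raw(c(0L, 0L)), con)            # arrow style/size
  wr2(0L)                                     # rounded rect arc
  wr4(0L)                                     # position
  h2_off <- 64L + 4L * n + 8L * n
  wr4(h2_off)
  wr2(round(v[, 1L]) - left)
  wr2(round(v[, 2L]) - top)
  writeBin(as.numeric(v[, 1L]), con, size = 4, endian = "big")
  writeBin(as.numeric(v[, 2L]), con, size = 4, endian = "big")
  # header2: zeros except the name fields
  nm <- polygon$name %||% ""
  name_off <- if (nzchar(nm)) h2_off + 64L else 0L
  name_len <- if (nzchar(nm)) length(utf8ToInt(nm)) else 0L
  h2 <- integer(16)
  h2[5L] <- name_off                          # bytes 16-19
  h2[6L] <- name_len                          # bytes 20-23
  wr4(h2)
  if (nzchar(nm)) wr2(utf8ToInt(nm))
  blob <- rawConnectionValue(con)
  if (!is.null(path)) {
    writeBin(blob, path)
    return(invisible(blob))
  }
  blob
}
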