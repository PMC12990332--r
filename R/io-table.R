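# The printed column dialect of the morphometric table. ASCII renderings
# ("um", "um^2", "um-1") are written; Unicode micro/minus spellings are
# normalized away on read. The header "Inflections Points" is kept verbatim
# from the printed table.
.feature_table_headers <- c(
  "File", "Pixel size [um]", "Area [um^2]", "Perimeter [um]",
  "Average radius [um]", "Roundness", "Aspect Ratio", "Feret [um]",
  "MinFeret [um]", "Circularity", "Inflections Points",
  "Weighted curvature [um-1]", "DNE", "Transparency",
  "Mean curvature [um-1]", "Std curvature [um-1]", "R0 x Std curvature")

.feature_table_internal <- c(
  "file", "pixel_size", "area", "perimeter", "average_radius", "roundness",
  "aspect_ratio", "feret", "min_feret", "circularity", "inflection_points",
  "weighted_curvature", "dne", "transparency", "mean_curvature",
  "std_curvature", "r0_std_curvature")

normalize_header <- function(h) {
  h <- gsub("μ|µ", "u", h)       # Greek mu / micro sign
  h <- gsub("−|–", "-", h)       # Unicode minus / en-dash
  h <- gsub("\\s+", " ", trimws(h))
  h <- gsub("\\[ ", "[", h)
  gsub(" \\]", "]", h)
}

#' Write a morphometric feature table
#'
#' CSV in the printed column dialect: `File`, the pixel size and the 16
#' descriptors, one row per organoid.
#'
#' @param records `morphometric_record` rows (a data.frame).
#' @param path destination CSV.
#' @export
write_feature_table <- function(records, path) {
  missing_cols <- setdiff(.feature_table_internal, names(records))
  if (length(missing_cols))
    ms_schema(paste("records are missing columns:",
                    paste(missing_cols, collapse = ", ")))
  out <- records[, .feature_table_internal]
  names(out) <- .feature_table_headers
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a morphometric feature table
#'
#' Reads the CSV dialect written by [write_feature_table()]. Headers may use
#' either ASCII or Unicode micron spellings; column order is enforced and
#' the first out-of-place header is reported. With `transpose = TRUE` the
#' file is expected in the orientation prepared for the PCA step
#' (parameters as rows, samples as columns) and is transposed back.
#'
#' @param path CSV file.
#' @param transpose the file stores parameters as rows.
#' @return data.frame of `morphometric_record` rows, including the derived
#'   size-normalized `dne_r0` column.
#' @export
read_feature_table <- function(path, transpose = FALSE) {
  if (!file.exists(path)) ms_io(sprintf("cannot read '%s': no such file", path))
  if (transpose) {
    raw <- utils::read.csv(path, check.names = FALSE, row.names = 1L,
                           fileEncoding = "UTF-8")
    df <- as.data.frame(t(as.matrix(raw)), stringsAsFactors = FALSE)
    df <- data.frame(File = rownames(df), df, check.names = FALSE)
    hdr <- c("File", rownames(raw))
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    hdr <- names(df)
  }
  hn <- normalize_header(hdr)
  expect <- normalize_header(.feature_table_headers)
  # tolerate the alternative singular spelling of the inflection header
  hn[hn == "Inflection Points"] <- "Inflections Points"
  if (length(hn) != length(expect) || any(hn != expect)) {
    bad <- which(hn[seq_len(min(length(hn), length(expect)))] !=
                   expect[seq_len(min(length(hn), length(expect)))])[1L]
    if (is.na(bad)) bad <- min(length(hn), length(expect)) + 1L
    ms_schema(sprintf(
      "feature table schema mismatch at column %d: found '%s', expected '%s'",
      bad, if (bad <= length(hdr)) hdr[bad] else "<missing>", .feature_table_headers[bad]))
  }
  names(df) <- .feature_table_internal
  for (cn in setdiff(.feature_table_internal, "file"))
    df[[cn]] <- as.numeric(df[[cn]])
  num <- as.matrix(df[, setdiff(.feature_table_internal, "file")])
  if (any(!is.finite(num)))
    ms_validation("feature table contains non-finite numeric values")
  df$dne_r0 <- df$dne * df$average_radius
  class(df) <- c("morphometric_record", "data.frame")
  df
}
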