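#' Default analysis feature set
#'
#' The nine descriptors carried into the morphospace, in table order:
#' size (area, perimeter, Feret), shape (roundness, circularity), surface
#' complexity (inflection points, size-normalized DNExR0 and
#' R0 x Std curvature) and texture (transparency). Redundant or relatively
#' uninformative descriptors (pixel size, average radius, aspect ratio,
#' MinFeret, weighted and mean curvature) are excluded by default.
#'
#' @return character vector of feature display names.
#' @export
analysis_features <- function() {
  c("Area [um^2]", "Perimeter [um]", "Feret [um]", "Roundness", "Circularity",
    "Inflection Points", "DNExR0", "R0 x Std curvature", "Transparency")
}

.analysis_feature_map <- c(
  "Area [um^2]" = "area", "Perimeter [um]" = "perimeter",
  "Average radius [um]" = "average_radius", "Roundness" = "roundness",
  "Aspect Ratio" = "aspect_ratio", "Feret [um]" = "feret",
  "MinFeret [um]" = "min_feret", "Circularity" = "circularity",
  "Inflection Points" = "inflection_points",
  "Inflections Points" = "inflection_points",
  "Weighted curvature [um-1]" = "weighted_curvature", "DNE" = "dne",
  "Transparency" = "transparency", "Mean curvature [um-1]" = "mean_curvature",
  "Std curvature [um-1]" = "std_curvature",
  "R0 x Std curvature" = "r0_std_curvature", "DNExR0" = "dne_r0",
  "Pixel size [um]" = "pixel_size")

#' Assemble the feature matrix for the morphospace
#'
#' Selects the analysis features from measured records and returns a
#' samples-by-features matrix. Features can be named either by their table
#' display names (see [analysis_features()]) or by the internal record
#' column names.
#'
#' @param records `morphometric_record` rows (data.frame); the derived
#'   `dne_r0` column is computed from `dne` and `average_radius` if absent.
#' @param include features to keep, in order.
#' @param role optional per-sample labels (`"reference"` / `"input"`).
#' @return object of class `feature_matrix`: list with `values`
#'   (samples x features), `sample_ids`, `feature_names`, `role`.
#' @export
select_features <- function(records, include = analysis_features(), role = NULL) {
  records <- as.data.frame(records)
  if (!nrow(records)) ms_validation("no records supplied")
  if (is.null(records$dne_r0) && !is.null(records$dne) &&
      !is.null(records$average_radius))
    records$dne_r0 <- records$dne * records$average_radius
  internal <- ifelse(include %in% names(.analysis_feature_map),
                     .analysis_feature_map[include], include)
  missing_f <- include[!internal %in% names(records)]
  if (length(missing_f))
    ms_schema(paste("requested feature(s) absent from records:",
                    paste(missing_f, collapse = ", ")))
  vals <- as.matrix(records[, internal, drop = FALSE])
  storage.mode(vals) <- "double"
  display <- ifelse(include %in% names(.analysis_feature_map), include,
                    names(.analysis_feature_map)[match(include, .analysis_feature_map)])
  colnames(vals) <- display
  ids <- if (!is.null(records$file) && !anyDuplicated(records$file) &&
             all(nzchar(records$file))) records$file else
    sprintf("sample_%02d", seq_len(nrow(records)))
  rownames(vals) <- ids
  if (!all(is.finite(vals)))
    ms_validation("feature matrix contains missing or non-finite values")
  if (nrow(vals) >= 2L) {
    v <- apply(vals, 2L, stats::var)
    if (any(v == 0))
      ms_validation(paste("zero-variance feature(s):",
                          paste(colnames(vals)[v == 0], collapse = ", "),
                          "- these cannot be scaled"))
  }
  structure(list(values = vals, sample_ids = ids, feature_names = colnames(vals),
                 role = role %||% rep("input", nrow(vals))),
            class = "feature_matrix")
}

#' Standardize a feature matrix
#'
#' Centers each feature to mean 0 and scales to unit sample standard
#' deviation (n - 1 denominator, the `prcomp(scale = TRUE)` convention).
#'
#' @param fm a [select_features()] matrix.
#' @return the matrix with standardized `values` and attributes `center`
#'   and `scale`.
#' @export
standardize <- function(fm) {
  ctr <- colMeans(fm$values)
  scl <- apply(fm$values, 2L, stats::sd)
  if (any(scl == 0))
    ms_validation(paste("zero-variance feature(s):",
                        paste(fm$feature_names[scl == 0], collapse = ", ")))
  fm$values <- scale(fm$values, center = ctr, scale = scl)
  attr(fm$values, "scaled:center") <- NULL
  attr(fm$values, "scaled:scale") <- NULL
  fm$center <- ctr
  fm$scale <- scl
  fm
}

#' Principal-component morphospace
#'
#' Scaled PCA of the feature matrix via `prcomp`: each feature is centered
#' and scaled to unit variance, components are ordered by decreasing
#' variance, and the per-component percent variance and the variable cos^2
#' (quality of representation) table are derived. Component signs are fixed
#' deterministically: the largest-magnitude loading of each component is
#' made positive, so results are reproducible across runs and platforms.
#'
#' @param fm a [select_features()] matrix.
#' @param scale scale features to unit variance (the reference workflow
#'   always scales).
#' @return object of class `morphospace_model`: `scores`
#'   (samples x components), `loadings` (features x components), `sdev`,
#'   `var_pct`, `cos2`, `center`, `scale`, `sample_ids`, `feature_names`,
#'   `role`.
#' @export
pca_morphospace <- function(fm, scale = TRUE) {
  if (nrow(fm$values) < 2L) ms_validation("PCA needs at least 2 samples")
  if (scale) {
    v <- apply(fm$values, 2L, stats::var)
    if (any(v == 0))
      ms_validation(paste("zero-variance feature(s):",
                          paste(fm$feature_names[v == 0], collapse = ", ")))
  }
  pc <- stats::prcomp(fm$values, center = TRUE, scale. = scale)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  cos2 <- sweep(pc$rotation, 2L, pc$sdev, `*`)^2
  structure(list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
                 var_pct = var_pct, cos2 = cos2,
                 center = pc$center,
                 scale = if (scale) pc$scale else rep(1, ncol(fm$values)),
                 sample_ids = fm$sample_ids, feature_names = fm$feature_names,
                 role = fm$role, scaled = scale),
            class = "morphospace_model")
}

#' @export
print.morphospace_model <- function(x, ...) {
  cat(sprintf("<morphospace_model> %d samples, %d features, %d components\n",
              nrow(x$scores), length(x$feature_names), length(x$sdev)))
  cat("variance explained (%):",
      paste(sprintf("%.1f", x$var_pct[seq_len(min(5L, length(x$var_pct)))]),
            collapse = ", "),
      if (length(x$var_pct) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Variable cos-squared table
#'
#' Quality of representation of each feature on each component:
#' `cos2[f, c] = (loading[f, c] * sdev[c])^2`. For scaled (correlation) PCA
#' each feature's row sums to 1 over all components.
#'
#' @param model a [pca_morphospace()] model.
#' @return features x components matrix.
#' @export
variable_cos2 <- function(model) model$cos2
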