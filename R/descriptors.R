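#' Geometry configuration for organoid measurement
#'
#' Tunable numerical parameters of the contour-measurement pipeline.
#'
#' @param n_samples uniform arclength samples used for differentiation.
#' @param smooth_frac boundary Gaussian smoothing scale as a fraction of the
#'   perimeter (0 disables). The default 1% suppresses pixelation noise on
#'   rasterized boundaries; use 0 for exact analytic contours.
#' @param min_arc_frac inflection persistence floor as a fraction of the
#'   perimeter.
#' @param log_base base of the DNE logarithm, `"natural"` or `"log10"`.
#' @param std_curvature_mode `"kappa"` (standard deviation of the per-point
#'   signed curvature, 1/micron) or `"log_energy"` (standard deviation of
#'   the per-point log squared-curvature contribution, an alternative
#'   reading of the descriptor's prose definition).
#' @param log_sigma_px Laplacian-of-Gaussian scale for the transparency
#'   descriptor, in pixels.
#' @param check_simple run the exact self-intersection test on every input
#'   contour (quadratic cost; intended for manual ROIs).
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(n_samples = 1024L,
                            smooth_frac = 0.01,
                            min_arc_frac = 0.02,
                            log_base = c("natural", "log10"),
                            std_curvature_mode = c("kappa", "log_energy"),
                            log_sigma_px = 2,
                            check_simple = FALSE) {
  stopifnot(n_samples >= 16L, smooth_frac >= 0, min_arc_frac >= 0, log_sigma_px > 0)
  structure(list(n_samples = as.integer(n_samples), smooth_frac = smooth_frac,
                 min_arc_frac = min_arc_frac, log_base = match.arg(log_base),
                 std_curvature_mode = match.arg(std_curvature_mode),
                 log_sigma_px = log_sigma_px, check_simple = isTRUE(check_simple)),
            class = "geometry_config")
}

#' Area and perimeter of a closed contour
#'
#' Shoelace area and summed edge lengths.
#'
#' @param contour counterclockwise simple closed contour (microns).
#' @param check run the exact (quadratic) self-intersection test first.
#' @return named numeric `area` (um^2) and `perimeter` (um).
#' @export
polygon_area_perimeter <- function(contour, check = FALSE) {
  if (check && !is_simple_polygon(contour))
    ms_validation("contour is self-intersecting")
  a <- signed_area(contour)
  if (a <= 0) ms_validation("contour must be counterclockwise with positive area")
  c(area = a, perimeter = sum(edge_lengths(contour)))
}

#' Feret (caliper) diameters
#'
#' Maximum Feret diameter: the longest distance between any two boundary
#' points, computed as the diameter of the convex hull. Minimum Feret: the
#' smallest width between two parallel supporting lines, minimized over
#' hull-edge-aligned directions (the minimum width of a convex polygon is
#' always attained flush with one of its edges).
#'
#' @param contour closed contour with at least 3 points.
#' @return named numeric `feret`, `min_feret` (microns).
#' @export
feret_diameters <- function(contour) {
  p <- unclass(contour)
  if (nrow(p) < 3L) ms_validation("Feret diameters need at least 3 points")
  h <- grDevices::chull(p[, 1L], p[, 2L])
  hp <- p[h, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3L) ms_validation("degenerate (collinear) contour")
  dmat <- as.matrix(stats::dist(hp))
  feret <- max(dmat)
  i2 <- c(2:m, 1L)
  ex <- hp[i2, 1L] - hp[, 1L]
  ey <- hp[i2, 2L] - hp[, 2L]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  widths <- vapply(which(keep), function(i) {
    nx <- -ey[i] / len[i]; ny <- ex[i] / len[i]      # unit normal of edge i
    pr <- hp[, 1L] * nx + hp[, 2L] * ny
    max(pr) - min(pr)
  }, numeric(1))
  c(feret = feret, min_feret = min(widths))
}

#' Roundness, aspect ratio and major axis from the equivalent ellipse
#'
#' Axes come from the area-moment (second central moment) equivalent
#' ellipse, the convention behind ImageJ's "Major"/"Minor" measurements:
#' semi-axes are `2*sqrt(lambda)` for the eigenvalues of the normalized
#' covariance of the region. Roundness = 4*Area / (pi * Major^2);
#' aspect ratio = Major/Minor (>= 1). The axis-aligned bounding-box
#' width/height ratio is reported alongside as `bbox_aspect` for the
#' literal "width to height" reading.
#'
#' @param contour simple closed contour.
#' @return named numeric `roundness`, `aspect_ratio`, `major_axis` (um),
#'   `minor_axis` (um), `bbox_aspect`.
#' @export
ellipse_shape_factors <- function(contour) {
  m <- polygon_moments(contour)
  cv <- matrix(c(m$mu20, m$mu11, m$mu11, m$mu02), 2L)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] <= 0) ms_validation("zero second moment; contour is degenerate")
  major <- 4 * sqrt(ev[1L])
  minor <- 4 * sqrt(max(ev[2L], 0))
  p <- unclass(contour)
  bw <- diff(range(p[, 1L])); bh <- diff(range(p[, 2L]))
  c(roundness = 4 * m$area / (pi * major^2),
    aspect_ratio = if (minor > 0) major / minor else Inf,
    major_axis = major, minor_axis = minor,
    bbox_aspect = bw / bh)
}

#' Circularity
#'
#' 4*pi*Area / Perimeter^2: 1 for a circle, lower for elongated or lobed
#' shapes. The raw value is returned; values may exceed 1 by a small
#' discretization allowance on coarse polygons.
#'
#' @param area region area (um^2).
#' @param perimeter boundary length (um).
#' @export
circularity <- function(area, perimeter) {
  stopifnot(area > 0, perimeter > 0)
  4 * pi * area / perimeter^2
}

# Scale-normalized Laplacian-of-Gaussian kernel (zero DC response).
log_kernel <- function(sigma) {
  half <- max(3L, ceiling(3 * sigma))
  xs <- (-half):half
  g <- outer(xs, xs, function(x, y) {
    r2 <- x^2 + y^2
    (r2 - 2 * sigma^2) / (2 * pi * sigma^6) * exp(-r2 / (2 * sigma^2))
  })
  g <- g - mean(g)            # exact zero response to constants
  g * sigma^2                 # scale normalization for comparability
}

#' Transparency: mean Laplacian-of-Gaussian response inside the organoid
#'
#' The more transparent the neuroepithelium, the more textured the
#' brightfield image and the higher the filter response. Computed as the
#' mean absolute scale-normalized LoG response over the mask interior,
#' eroded by 2 px to avoid gradient leakage from the boundary.
#'
#' @param image a [calibrated_image()].
#' @param mask a [binary_mask()] congruent with the image.
#' @param log_sigma_px LoG scale in pixels.
#' @param aggregate `"abs"` (default), `"square"` (root mean squared
#'   response) or `"signed"` (plain mean).
#' @return mean response in intensity units.
#' @export
transparency <- function(image, mask, log_sigma_px = 2,
                         aggregate = c("abs", "square", "signed")) {
  aggregate <- match.arg(aggregate)
  px <- mask$pixels
  if (!any(px)) ms_validation("empty mask")
  if (!all(dim(px) == dim(image$pixels)))
    ms_validation("mask and image dimensions differ")
  k <- log_kernel(log_sigma_px)
  resp <- EBImage::filter2(image$pixels, k, boundary = "replicate")
  er <- EBImage::erode(px * 1, EBImage::makeBrush(5L, shape = "disc"))
  sel <- er > 0.5
  if (!any(sel)) sel <- px    # mask thinner than the erosion margin
  v <- resp[sel]
  switch(aggregate,
         abs = mean(abs(v)),
         square = sqrt(mean(v^2)),
         signed = mean(v))
}

#' Measure one organoid: the full morphometric record
#'
#' Assembles the complete descriptor set from a closed contour and,
#' when an image is supplied, the texture descriptor from the pixels
#' inside it. The geometric pipeline is: uniform arclength resampling,
#' optional periodic Gaussian boundary smoothing, a second resampling,
#' periodic central differences, signed curvature, and the derived
#' summaries. Size-normalized surface-complexity scores DNExR0 and
#' R0 x Std curvature are included.
#'
#' @param contour closed counterclockwise contour in microns.
#' @param image optional [calibrated_image()]; when missing the
#'   transparency field is `NA`.
#' @param mask optional [binary_mask()]; rasterized from the contour when an
#'   image is given without one.
#' @param config a [geometry_config()].
#' @param file sample identifier stored in the record.
#' @param pixel_size microns per pixel recorded alongside; taken from
#'   `image` when available.
#' @return one-row data.frame of class `morphometric_record`.
#' @export
measure_organoid <- function(contour, image = NULL, mask = NULL,
                             config = geometry_config(), file = "",
                             pixel_size = NA_real_) {
  if (config$check_simple && !is_simple_polygon(contour))
    ms_validation(sprintf("contour of '%s' is self-intersecting", file))
  res <- try({
    cc <- resample_closed_contour(contour, config$n_samples)
    ap0 <- polygon_area_perimeter(cc)
    if (config$smooth_frac > 0) {
      cc <- smooth_closed_contour(cc, config$smooth_frac * ap0[["perimeter"]])
      cc <- resample_closed_contour(cc, config$n_samples)
    }
    ap <- polygon_area_perimeter(cc)
    dv <- contour_derivatives(cc)
    pr <- curvature_profile(dv)
    cs <- curvature_summaries(pr, dv)
    fer <- feret_diameters(cc)
    ell <- ellipse_shape_factors(cc)
    r0 <- average_radius(cc, config$n_samples)
    std_c <- if (config$std_curvature_mode == "kappa") {
      cs[["std_curvature"]]
    } else {
      stats::sd(log(pmax(pr$kappa^2 * dv$seg_len, .Machine$double.xmin)))
    }
    dne <- as.numeric(dirichlet_normal_energy(pr, dv, config$log_base))
    infl <- as.integer(count_inflection_points(pr, config$min_arc_frac * ap[["perimeter"]]))
    transp <- NA_real_
    if (!is.null(image)) {
      if (is.null(mask)) mask <- contour_to_mask(contour, image)
      transp <- transparency(image, mask, config$log_sigma_px)
      pixel_size <- image$pixel_size
    } else if (!is.null(mask)) {
      pixel_size <- mask$pixel_size
    }
    data.frame(file = file, pixel_size = pixel_size,
               area = ap[["area"]], perimeter = ap[["perimeter"]],
               average_radius = r0,
               roundness = ell[["roundness"]], aspect_ratio = ell[["aspect_ratio"]],
               feret = fer[["feret"]], min_feret = fer[["min_feret"]],
               circularity = circularity(ap[["area"]], ap[["perimeter"]]),
               inflection_points = infl,
               weighted_curvature = cs[["weighted_curvature"]],
               dne = dne, transparency = transp,
               mean_curvature = cs[["mean_curvature"]], std_curvature = std_c,
               r0_std_curvature = std_c * r0, dne_r0 = dne * r0,
               stringsAsFactors = FALSE)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    ms_validation(sprintf("measurement of '%s' failed: %s", file,
                          conditionMessage(attr(res, "condition"))))
  class(res) <- c("morphometric_record", "data.frame")
  res
}

# Rasterize a contour (micron, y-up) onto the image grid as a binary mask.
# Even-odd rule over the bounding box of the polygon.
contour_to_mask <- function(contour, image) {
  ps <- image$pixel_size
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  p <- unclass(contour)
  vx <- p[, 1L] / ps                 # 0-based pixel x
  vy <- (H - 1) - p[, 2L] / ps       # 0-based pixel row (y down)
  xs <- max(0L, floor(min(vx))):min(W - 1L, ceiling(max(vx)))
  ys <- max(0L, floor(min(vy))):min(H - 1L, ceiling(max(vy)))
  inside <- matrix(FALSE, length(ys), length(xs))
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  n <- length(vx)
  j <- c(n, 1:(n - 1L))
  cross_count <- rep(0L, length(gx))
  for (i in seq_len(n)) {
    x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[j[i]]; y2 <- vy[j[i]]
    if (y1 == y2) next
    cond <- (y1 > gy) != (y2 > gy)
    if (!any(cond)) next
    xin <- x1 + (gy[cond] - y1) / (y2 - y1) * (x2 - x1)
    hit <- which(cond)[gx[cond] < xin]
    cross_count[hit] <- cross_count[hit] + 1L
  }
  inside[] <- (cross_count %% 2L) == 1L
  full <- matrix(FALSE, H, W)
  full[ys + 1L, xs + 1L] <- inside
  binary_mask(full, ps)
}
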