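#' Binary organoid mask
#'
#' @param pixels logical matrix congruent with the source image.
#' @param pixel_size microns per pixel.
#' @export
binary_mask <- function(pixels, pixel_size) {
  if (!is.matrix(pixels)) ms_validation("mask pixels must be a matrix")
  structure(list(pixels = pixels > 0, pixel_size = pixel_size),
            class = "binary_mask")
}

#' Segmentation parameters
#'
#' The automated segmentation is a classical intensity pipeline:
#' Gaussian pre-smoothing, global threshold (Otsu by default), morphological
#' closing, hole filling, and selection of the largest connected component.
#' All knobs are exposed so the behaviour can be matched empirically to a
#' given imaging setup.
#'
#' @param blur_sigma_px Gaussian pre-smoothing scale (pixels).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold raw-intensity threshold, used iff `method = "fixed"`.
#' @param min_area_fraction minimum object area as a fraction of image area.
#' @param fill_holes fill interior holes of the mask.
#' @param closing_radius_px morphological closing radius (pixels).
#' @param polarity `"dark_object"`, `"light_object"` or `"auto"`. Auto picks
#'   the polarity whose largest component does not touch 3 or more image
#'   borders (brightfield organoids are dark objects on a light field).
#' @param refine_boundary half-maximum boundary refinement: after the
#'   initial mask, re-threshold at the midpoint between the median
#'   intensity just inside and just outside the boundary. A global Otsu cut
#'   crosses a blurred edge away from its midpoint whenever the object
#'   interior is broadly shaded, biasing the boundary inward or outward by
#'   a pixel or so; the midpoint cut removes that bias.
#' @export
segmentation_params <- function(blur_sigma_px = 2.0,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area_fraction = 0.005,
                                fill_holes = TRUE,
                                closing_radius_px = 3L,
                                polarity = c("auto", "dark_object", "light_object"),
                                refine_boundary = TRUE) {
  stopifnot(blur_sigma_px >= 0, min_area_fraction > 0, min_area_fraction < 1)
  structure(list(blur_sigma_px = blur_sigma_px,
                 threshold_method = match.arg(threshold_method),
                 fixed_threshold = fixed_threshold,
                 min_area_fraction = min_area_fraction,
                 fill_holes = isTRUE(fill_holes),
                 closing_radius_px = as.integer(closing_radius_px),
                 polarity = match.arg(polarity),
                 refine_boundary = isTRUE(refine_boundary)),
            class = "segmentation_params")
}

#' Automatically segment one organoid from a calibrated image
#'
#' Thresholds the blurred image, cleans the mask morphologically, and keeps
#' the largest connected component. Conditions that the printed workflow
#' handles by falling back to manual tracing are surfaced as errors (no
#' component passing the area floor) or warnings attached to the result
#' (border contact; a second component of comparable size, suggesting more
#' than one organoid in the field of view).
#'
#' @param image a [calibrated_image()].
#' @param params a [segmentation_params()].
#' @return a [binary_mask()] with a `warnings` attribute (character).
#' @export
auto_segment <- function(image, params = segmentation_params()) {
  px <- image$pixels
  top <- if (image$bit_depth < 32L) 2^image$bit_depth - 1 else max(px)
  lo <- if (image$bit_depth < 32L) 0 else min(px)
  img01 <- (px - lo) / max(top - lo, .Machine$double.eps)
  sm <- img01
  if (params$blur_sigma_px > 0)
    sm <- as.matrix(EBImage::gblur(img01, sigma = params$blur_sigma_px))
  thr <- if (params$threshold_method == "otsu") {
    EBImage::otsu(EBImage::Image(sm), range = range(sm), levels = 256L)
  } else {
    if (is.null(params$fixed_threshold))
      ms_validation("threshold_method = 'fixed' needs fixed_threshold")
    (params$fixed_threshold - lo) / (top - lo)
  }
  polarities <- switch(params$polarity,
                       dark_object = "dark", light_object = "light",
                       auto = c("dark", "light"))
  floor_px <- params$min_area_fraction * length(px)
  cand <- lapply(polarities, function(pol) {
    m <- if (pol == "dark") sm < thr else sm > thr
    postprocess_mask(m, params, floor_px)
  })
  names(cand) <- polarities
  ok <- vapply(cand, function(cc) !is.null(cc) && cc$borders < 3L, logical(1))
  pick <- if (any(ok)) which(ok)[1L] else which(!vapply(cand, is.null, logical(1)))[1L]
  if (is.na(pick) || length(pick) == 0L)
    ms_stop("no object passes the minimum-area floor; discard the image or segment manually",
            "morphoscreen_empty_segmentation")
  cc <- cand[[pick]]
  if (params$refine_boundary) {
    dark <- names(cand)[pick] == "dark"
    refined <- refine_halfmax(sm, cc$mask, dark, params, floor_px)
    if (!is.null(refined)) cc <- refined
  }
  warnings <- character(0)
  if (cc$borders > 0L)
    warnings <- c(warnings, sprintf("organoid touches %d image border(s)", cc$borders))
  if (cc$second_area / cc$area > 0.5)
    warnings <- c(warnings,
                  "ambiguous segmentation: a second component has more than half the area of the largest (more than one organoid in the field?)")
  out <- binary_mask(cc$mask, image$pixel_size)
  attr(out, "warnings") <- warnings
  out
}

postprocess_mask <- function(m, params, floor_px) {
  m <- m * 1
  if (params$closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * params$closing_radius_px + 1L, shape = "disc")
    m <- as.matrix(EBImage::closing(m, brush))
  }
  if (params$fill_holes) m <- as.matrix(EBImage::fillHull(m))
  lab <- as.matrix(EBImage::bwlabel(m))
  if (max(lab) == 0L) return(NULL)
  areas <- tabulate(lab[lab > 0])
  best <- which.max(areas)
  if (areas[best] < floor_px) return(NULL)
  mask <- lab == best
  borders <- sum(any(mask[1L, ]), any(mask[nrow(mask), ]),
                 any(mask[, 1L]), any(mask[, ncol(mask)]))
  list(mask = mask, area = areas[best],
       second_area = if (length(areas) > 1L) max(areas[-best]) else 0,
       borders = borders)
}

# Half-maximum refinement: cut the blurred image at the midpoint of the
# median levels in thin bands just inside and just outside the initial
# boundary, then re-clean. Falls back to the initial mask (NULL) if the
# refined cut loses the object.
refine_halfmax <- function(sm, mask, dark, params, floor_px) {
  m <- mask * 1
  near <- EBImage::makeBrush(9L, shape = "disc")    # radius 4: clears the blurred edge
  far <- EBImage::makeBrush(17L, shape = "disc")    # radius 8
  inner <- as.matrix(EBImage::erode(m, near)) - as.matrix(EBImage::erode(m, far))
  outer <- as.matrix(EBImage::dilate(m, far)) - as.matrix(EBImage::dilate(m, near))
  if (sum(inner) < 10 || sum(outer) < 10) return(NULL)
  lvl_in <- stats::median(sm[inner > 0])
  lvl_out <- stats::median(sm[outer > 0])
  iso <- (lvl_in + lvl_out) / 2
  m2 <- if (dark) sm < iso else sm > iso
  postprocess_mask(m2, params, floor_px)
}

#' Extract the closed outer contour of a mask
#'
#' Marching-squares boundary at the 0.5 iso-level of the binary mask
#' (sub-pixel, smoother curvature estimates than pixel-corner chains),
#' converted to microns in a y-up mathematical frame and oriented
#' counterclockwise.
#'
#' @param mask a [binary_mask()] with exactly one connected component.
#' @return a [as_contour()] object.
#' @export
mask_to_contour <- function(mask) {
  m <- mask$pixels * 1
  lab <- as.matrix(EBImage::bwlabel(m))
  ncomp <- max(lab)
  if (ncomp == 0L) ms_validation("mask is empty")
  if (ncomp > 1L)
    ms_validation(sprintf("mask has %d components; exactly one expected", ncomp))
  H <- nrow(m); W <- ncol(m)
  padded <- matrix(0, H + 2L, W + 2L)
  padded[2:(H + 1L), 2:(W + 1L)] <- m
  cl <- grDevices::contourLines(x = -1:W, y = -1:H, z = t(padded), levels = 0.5)
  if (!length(cl)) ms_validation("no iso-contour found at level 0.5")
  areas <- vapply(cl, function(cc) {
    p <- cbind(cc$x, cc$y)
    if (nrow(p) < 3L) return(0)
    abs(signed_area(p))
  }, numeric(1))
  cc <- cl[[which.max(areas)]]
  p <- cbind(cc$x, cc$y)
  if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  ps <- mask$pixel_size
  as_contour(cbind(p[, 1L] * ps, ((H - 1) - p[, 2L]) * ps))
}

#' Convert a manual ROI polygon to a contour
#'
#' Transforms ImageJ pixel coordinates (y down) to microns in the y-up
#' frame, drops a repeated closing vertex, rejects self-intersecting
#' polygons, and normalizes the orientation to counterclockwise.
#'
#' @param polygon a [roi_polygon()].
#' @param pixel_size microns per pixel.
#' @param image_height raster height in pixels, used to place the y-up
#'   origin at the image bottom; when `NULL` the y axis is simply negated.
#' @export
roi_to_contour <- function(polygon, pixel_size, image_height = NULL) {
  if (!inherits(polygon, "roi_polygon")) ms_validation("polygon must be an roi_polygon")
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    ms_validation("pixel_size must be a positive scalar")
  v <- polygon$vertices
  yup <- if (is.null(image_height)) -v[, 2L] else (image_height - 1) - v[, 2L]
  p <- cbind(v[, 1L] * pixel_size, yup * pixel_size)
  ct <- as_contour(p, normalize = FALSE)
  if (!is_simple_polygon(ct))
    ms_validation(sprintf("ROI '%s' is self-intersecting", polygon$name))
  as_contour(unclass(ct), normalize = TRUE)
}
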