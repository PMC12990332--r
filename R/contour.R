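#' Closed planar contours
#'
#' A contour is the closed outer boundary of an organoid: an ordered set of
#' (x, y) vertices in microns, counterclockwise in a y-up mathematical frame,
#' with the closing edge from the last vertex back to the first implied.
#'
#' @param points two-column numeric matrix (x, y) in microns.
#' @param normalize reverse the vertex order if the polygon is clockwise.
#' @return object of class `contour`: the vertex matrix with columns `x`, `y`.
#' @export
as_contour <- function(points, normalize = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L)
    ms_validation("a contour needs at least 3 (x, y) vertices")
  if (!all(is.finite(points)))
    ms_validation("contour coordinates must be finite")
  colnames(points) <- c("x", "y")
  # drop consecutive duplicates, including a repeated closing vertex
  d <- rowSums(abs(points - points[c(2:nrow(points), 1L), , drop = FALSE]))
  if (any(d == 0)) points <- points[d > 0, , drop = FALSE]
  if (nrow(points) < 3L)
    ms_validation("contour degenerates to fewer than 3 distinct vertices")
  if (normalize && signed_area(points) < 0)
    points <- points[nrow(points):1L, , drop = FALSE]
  structure(points, class = c("contour", "matrix"))
}

#' @export
print.contour <- function(x, ...) {
  ap <- polygon_area_perimeter(x)
  cat(sprintf("<contour> %d vertices, area %.4g um^2, perimeter %.4g um\n",
              nrow(x), ap[["area"]], ap[["perimeter"]]))
  invisible(x)
}

# Shoelace signed area; > 0 for counterclockwise order (y-up frame).
signed_area <- function(p) {
  i2 <- c(2:nrow(p), 1L)
  sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L]) / 2
}

# Edge lengths, edge i running from vertex i to vertex i+1 (wrapping).
edge_lengths <- function(p) {
  i2 <- c(2:nrow(p), 1L)
  sqrt((p[i2, 1L] - p[, 1L])^2 + (p[i2, 2L] - p[, 2L])^2)
}

#' Resample a closed contour uniformly in arclength
#'
#' Linear interpolation along the polygon's edges at `n` equally spaced
#' arclength positions. Uniform spacing is a precondition of the
#' finite-difference derivative estimates used for curvature.
#'
#' @param contour a [as_contour()] object.
#' @param n number of samples (>= 16).
#' @return a `contour` with exactly `n` uniformly spaced vertices.
#' @export
resample_closed_contour <- function(contour, n = 1024L) {
  if (n < 16L) ms_validation("resampling needs n >= 16")
  p <- unclass(contour)
  el <- edge_lengths(p)
  L <- sum(el)
  if (L <= 0) ms_validation("zero-length contour cannot be resampled")
  s <- c(0, cumsum(el))                     # arclength at each vertex, closed
  px <- c(p[, 1L], p[1L, 1L])
  py <- c(p[, 2L], p[1L, 2L])
  st <- L * (0:(n - 1L)) / n
  out <- cbind(x = stats::approx(s, px, xout = st)$y,
               y = stats::approx(s, py, xout = st)$y)
  structure(out, class = c("contour", "matrix"))
}

#' Smooth a closed contour with a periodic Gaussian kernel
#'
#' x(s) and y(s) are circularly convolved with a Gaussian of standard
#' deviation `sigma_um` (arclength units). The kernel is normalized, so the
#' vertex centroid is preserved. `sigma_um = 0` is the identity.
#'
#' @param contour uniformly resampled contour.
#' @param sigma_um smoothing scale in microns along the boundary.
#' @export
smooth_closed_contour <- function(contour, sigma_um) {
  if (sigma_um < 0) ms_validation("sigma_um must be >= 0")
  if (sigma_um == 0) return(contour)
  p <- unclass(contour)
  n <- nrow(p)
  h <- mean(edge_lengths(p))
  sig <- sigma_um / h                        # kernel scale in samples
  off <- c(0:(n %/% 2), -((n - n %/% 2 - 1L):1L))
  k <- exp(-0.5 * (off / sig)^2)
  k <- k / sum(k)
  fk <- stats::fft(k)
  sm <- function(v) Re(stats::fft(stats::fft(v) * fk, inverse = TRUE)) / n
  structure(cbind(x = sm(p[, 1L]), y = sm(p[, 2L])),
            class = c("contour", "matrix"))
}

# Area, centroid and normalized central second moments of a simple closed
# polygon (Green's-theorem edge sums). Orientation-independent outputs.
polygon_moments <- function(p) {
  p <- unclass(p)
  i2 <- c(2:nrow(p), 1L)
  x <- p[, 1L]; y <- p[, 2L]; x2 <- p[i2, 1L]; y2 <- p[i2, 2L]
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps^0.5)
    ms_validation("polygon has (numerically) zero area")
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  Ix  <- sum((y^2 + y * y2 + y2^2) * cr) / 12          # integral of y^2 dA
  Iy  <- sum((x^2 + x * x2 + x2^2) * cr) / 12          # integral of x^2 dA
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  sgn <- sign(A)
  list(area = abs(A), cx = cx, cy = cy,
       mu20 = sgn * Iy / abs(A) - cx^2,
       mu02 = sgn * Ix / abs(A) - cy^2,
       mu11 = sgn * Ixy / abs(A) - cx * cy)
}

# Exact O(n^2) simple-polygon test (proper edge crossings). Intended for
# manual ROIs (hundreds of vertices); not run by default on dense contours.
is_simple_polygon <- function(p) {
  p <- unclass(p)
  n <- nrow(p)
  i2 <- c(2:n, 1L)
  ax <- p[, 1L]; ay <- p[, 2L]
  bx <- p[i2, 1L]; by <- p[i2, 2L]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]          # skip edges sharing a vertex
    if (!length(js)) next
    d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[js], ay[js])
    d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[js], by[js])
    d3 <- cross(ax[js], ay[js], bx[js], by[js], ax[i], ay[i])
    d4 <- cross(ax[js], ay[js], bx[js], by[js], bx[i], by[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}
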