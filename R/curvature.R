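#' Derivatives of a uniformly sampled closed contour
#'
#' Periodic central differences of x(s) and y(s) with respect to the
#' arclength parameter. On a uniformly resampled contour the
#' parameterization is unit speed, so dx^2 + dy^2 is approximately 1 and the
#' curvature denominator below is well conditioned.
#'
#' @param contour contour resampled to uniform arclength
#'   (spacing coefficient of variation must be below 5%).
#' @return list of class `derivative_set` with per-point `dx`, `dy`, `dxx`,
#'   `dyy` and local segment lengths `seg_len` (microns).
#' @export
contour_derivatives <- function(contour) {
  p <- unclass(contour)
  n <- nrow(p)
  el <- edge_lengths(p)
  h <- mean(el)
  if (stats::sd(el) / h > 0.05)
    ms_validation("contour sampling is non-uniform (spacing CV > 5%); resample first")
  ip <- c(2:n, 1L)           # i + 1
  im <- c(n, 1:(n - 1L))     # i - 1
  dx  <- (p[ip, 1L] - p[im, 1L]) / (2 * h)
  dy  <- (p[ip, 2L] - p[im, 2L]) / (2 * h)
  dxx <- (p[ip, 1L] - 2 * p[, 1L] + p[im, 1L]) / h^2
  dyy <- (p[ip, 2L] - 2 * p[, 2L] + p[im, 2L]) / h^2
  structure(list(dx = dx, dy = dy, dxx = dxx, dyy = dyy, seg_len = el),
            class = "derivative_set")
}

#' Signed curvature along a closed contour
#'
#' kappa = (dx * dyy - dy * dxx) / (dx^2 + dy^2)^(3/2), the inverse radius
#' of the tangent circle, positive on convex arcs of a counterclockwise
#' contour.
#'
#' @param derivs a [contour_derivatives()] result.
#' @return list of class `curvature_profile` with per-point `kappa`
#'   (1/micron) and cumulative arclength `arc_pos` (microns).
#' @export
curvature_profile <- function(derivs) {
  g <- derivs$dx^2 + derivs$dy^2
  if (any(g < 1e-12)) {
    ms_validation(sprintf("zero tangent magnitude at contour index %d",
                          which(g < 1e-12)[1L]))
  }
  kappa <- (derivs$dx * derivs$dyy - derivs$dy * derivs$dxx) / g^1.5
  structure(list(kappa = kappa,
                 arc_pos = cumsum(derivs$seg_len) - derivs$seg_len),
            class = "curvature_profile")
}

#' Curvature summary statistics
#'
#' Mean and standard deviation of the per-point signed curvature, and the
#' length-weighted curvature sum. For any simple closed counterclockwise
#' curve the weighted sum equals the total turning, 2*pi.
#'
#' @param profile a [curvature_profile()].
#' @param derivs the matching [contour_derivatives()].
#' @return named numeric: `mean_curvature`, `std_curvature` (1/micron),
#'   `weighted_curvature` (dimensionless sum of kappa * ds).
#' @export
curvature_summaries <- function(profile, derivs) {
  if (length(profile$kappa) != length(derivs$seg_len))
    ms_validation("profile and derivatives come from different contours")
  c(mean_curvature = mean(profile$kappa),
    std_curvature = stats::sd(profile$kappa),
    weighted_curvature = sum(profile$kappa * derivs$seg_len))
}

#' Count inflection points of a closed contour
#'
#' Counts sign changes of the signed curvature around the closed profile.
#' A persistence filter suppresses pixelation noise: a same-sign run shorter
#' than `min_arc_um` of arclength is merged into its neighbours before
#' counting, so every counted crossing is flanked by runs spanning at least
#' `min_arc_um`. The count is even for any closed curve.
#'
#' @param profile a [curvature_profile()] from a smoothed, uniformly
#'   resampled contour.
#' @param min_arc_um minimum persistence arclength in microns; the pipeline
#'   default is 2% of the perimeter.
#' @export
count_inflection_points <- function(profile, min_arc_um) {
  kappa <- profile$kappa
  if (all(abs(kappa) < 1e-12)) {
    return(structure(0L, degenerate = TRUE))
  }
  seg <- c(diff(profile$arc_pos), mean(diff(profile$arc_pos)))
  s <- sign(kappa)
  s[s == 0] <- 1L
  count_runs_with_persistence(s, seg, min_arc_um)
}

# Circular run-length simplification: repeatedly flip the shortest
# same-sign run below the persistence floor (merging it into its
# neighbours), then count the surviving runs -- the number of persistent
# sign changes, always even on a circle.
count_runs_with_persistence <- function(s, seg, min_arc) {
  n <- length(s)
  repeat {
    if (all(s == s[1L])) return(0L)
    st <- which(s != s[c(n, 1:(n - 1L))])[1L]   # rotate to a run boundary
    ord <- c(st:n, seq_len(st - 1L))
    r <- rle(s[ord])
    runs <- rep.int(seq_along(r$lengths), r$lengths)
    arc <- as.numeric(rowsum(seg[ord], runs))
    if (min(arc) >= min_arc) return(length(arc))
    w <- which.min(arc)
    s[ord[runs == w]] <- -r$values[w]
  }
}

#' Dirichlet normal energy of a closed contour
#'
#' Log-scale bending energy of the boundary: the variation of the unit
#' normal n = (dy, -dx) projected on the tangent t = (dx, dy). Under the
#' Frenet relations n'. t = -kappa, so the energy reduces to the arclength
#' integral of squared curvature and
#' DNE = log( sum_i kappa_i^2 * ds_i ).
#'
#' @param profile a [curvature_profile()].
#' @param derivs the matching [contour_derivatives()].
#' @param base `"natural"` (default) or `"log10"`.
#' @return scalar DNE (dimensionless, log scale). A numerically flat
#'   profile returns the log of the machine floor with attribute
#'   `degenerate = TRUE`.
#' @export
dirichlet_normal_energy <- function(profile, derivs, base = c("natural", "log10")) {
  base <- match.arg(base)
  e <- sum(profile$kappa^2 * derivs$seg_len)
  lg <- if (base == "natural") log else log10
  if (e <= .Machine$double.xmin)
    return(structure(lg(.Machine$double.xmin), degenerate = TRUE))
  lg(e)
}

#' Average radius R0
#'
#' Mean Euclidean distance from the area centroid to the uniformly
#' resampled boundary points.
#'
#' @param contour a closed contour.
#' @param n resampling density used for the boundary average.
#' @return R0 in microns.
#' @export
average_radius <- function(contour, n = 1024L) {
  m <- polygon_moments(contour)
  p <- unclass(resample_closed_contour(contour, n))
  mean(sqrt((p[, 1L] - m$cx)^2 + (p[, 2L] - m$cy)^2))
}
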