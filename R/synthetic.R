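#' Parametric organoid-like shape
#'
#' Polar-harmonic family r(theta) = R * (1 + sum_i a_i cos(n_i theta + phi_i)),
#' chosen because it admits closed-form curvature (the validation oracle)
#' while visually mimicking organoids with neural buds bulging from the
#' perimeter. Optional boundary jitter is realized at construction as a
#' band of random high-order harmonics (orders 9-24), so the radius
#' function is deterministic thereafter.
#'
#' @param base_radius R in microns.
#' @param lobes data.frame/matrix with columns `order` (integer >= 1),
#'   `amplitude` (fraction of R) and optionally `phase` (radians).
#' @param noise_amp total standard deviation of the jitter harmonics, as a
#'   fraction of R.
#' @param seed RNG seed used to realize the jitter harmonics.
#' @return object of class `shape_spec`.
#' @export
shape_spec <- function(base_radius = 450, lobes = NULL, noise_amp = 0,
                       seed = NULL) {
  if (!is_scalar_num(base_radius) || base_radius <= 0)
    ms_validation("base_radius must be positive")
  if (is.null(lobes)) {
    lobes <- data.frame(order = integer(0), amplitude = numeric(0),
                        phase = numeric(0))
  } else {
    lobes <- as.data.frame(lobes)
    if (is.null(lobes$phase)) lobes$phase <- 0
    if (any(lobes$order < 1) || any(lobes$order %% 1 != 0))
      ms_validation("lobe orders must be integers >= 1")
    if (any(lobes$amplitude < 0)) ms_validation("lobe amplitudes must be >= 0")
  }
  if (sum(lobes$amplitude) + 4 * noise_amp >= 0.45)
    ms_validation("total harmonic amplitude must stay below 0.45 to keep r > 0 (no self-intersection of the polar form)")
  noise <- data.frame(order = integer(0), amplitude = numeric(0),
                      phase = numeric(0))
  if (noise_amp > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    orders <- 9:24
    w <- abs(stats::rnorm(length(orders))) / orders   # red-tilted band
    amp <- noise_amp * w / sqrt(sum(w^2 / 2))         # sum of a^2/2 = variance
    noise <- data.frame(order = orders, amplitude = amp,
                        phase = stats::runif(length(orders), 0, 2 * pi))
  }
  structure(list(base_radius = base_radius, lobes = lobes, noise = noise,
                 noise_amp = noise_amp, seed = seed),
            class = "shape_spec")
}

# All harmonics (lobes + realized jitter) of a spec.
spec_harmonics <- function(spec) rbind(spec$lobes, spec$noise)

# Vectorized radius and its first two derivatives with respect to theta.
spec_radius <- function(spec, theta, deriv = 0L) {
  h <- spec_harmonics(spec)
  R <- spec$base_radius
  out <- if (deriv == 0L) rep(1, length(theta)) else rep(0, length(theta))
  for (i in seq_len(nrow(h))) {
    n <- h$order[i]; a <- h$amplitude[i]; ph <- h$phase[i]
    out <- out + switch(deriv + 1L,
                        a * cos(n * theta + ph),
                        -a * n * sin(n * theta + ph),
                        -a * n^2 * cos(n * theta + ph))
  }
  R * out
}

#' Sample a shape spec as a closed contour
#'
#' Evaluates the polar form on a dense angular grid and resamples to
#' uniform arclength. Counterclockwise by construction.
#'
#' @param spec a [shape_spec()].
#' @param n_samples contour samples after arclength resampling.
#' @export
shape_contour <- function(spec, n_samples = 2048L) {
  # invert arclength on a dense grid, then evaluate the polar form exactly
  # at the uniform-arclength angles: every emitted vertex lies on the
  # analytic curve (no chordal interpolation noise in downstream curvature)
  dense <- 16L * n_samples
  theta <- 2 * pi * (0:dense) / dense
  r <- spec_radius(spec, theta)
  if (any(r <= 0))
    ms_validation("radius function is non-positive; the parameterization self-intersects")
  rp <- spec_radius(spec, theta, 1L)
  speed <- sqrt(r^2 + rp^2)
  s <- c(0, cumsum((speed[-1L] + speed[-length(speed)]) / 2 * (2 * pi / dense)))
  st <- s[length(s)] * (0:(n_samples - 1L)) / n_samples
  th_i <- stats::approx(s, theta, xout = st)$y
  r_i <- spec_radius(spec, th_i)
  as_contour(cbind(r_i * cos(th_i), r_i * sin(th_i)), normalize = FALSE)
}

#' Closed-form morphometric oracle for a shape spec
#'
#' Geometry descriptors computed by high-resolution quadrature of the
#' closed-form polar expressions, independent of the discrete
#' differential-geometry pipeline: curvature is
#' kappa(theta) = (r^2 + 2 r'^2 - r r'') / (r^2 + r'^2)^(3/2), region
#' moments come from polar area integrals, inflection points from the sign
#' changes of the curvature numerator (with the same arclength persistence
#' floor the pipeline applies), and Feret widths from a dense directional
#' sweep.
#'
#' @param spec a [shape_spec()].
#' @param n_quad quadrature nodes over theta.
#' @param min_arc_frac persistence floor for inflection counting, as a
#'   fraction of the perimeter.
#' @return one-row data.frame with the geometry fields of a morphometric
#'   record (`transparency` is `NA`; there is no image).
#' @export
analytic_descriptors <- function(spec, n_quad = 16384L, min_arc_frac = 0.02) {
  th <- 2 * pi * (0:(n_quad - 1L)) / n_quad
  dth <- 2 * pi / n_quad
  r <- spec_radius(spec, th)
  rp <- spec_radius(spec, th, 1L)
  rpp <- spec_radius(spec, th, 2L)
  if (any(r <= 0)) ms_validation("radius function is non-positive")
  ds <- sqrt(r^2 + rp^2) * dth
  L <- sum(ds)
  A <- sum(r^2) * dth / 2
  cx <- sum(r^3 * cos(th)) * dth / (3 * A)
  cy <- sum(r^3 * sin(th)) * dth / (3 * A)
  x <- r * cos(th); y <- r * sin(th)
  r0 <- sum(sqrt((x - cx)^2 + (y - cy)^2) * ds) / L
  num <- r^2 + 2 * rp^2 - r * rpp
  kappa <- num / (r^2 + rp^2)^1.5
  mean_k <- sum(kappa * ds) / L
  std_k <- sqrt(sum((kappa - mean_k)^2 * ds) / L)
  weighted <- sum(kappa * ds)
  energy <- sum(kappa^2 * ds)
  dne <- log(energy)
  s <- sign(num)
  s[s == 0] <- 1L
  infl <- count_runs_with_persistence(s, ds, min_arc_frac * L)
  # region second moments about the centroid, from polar area integrals
  Ixx <- sum(r^4 * cos(th)^2) * dth / 4 - A * cx^2
  Iyy <- sum(r^4 * sin(th)^2) * dth / 4 - A * cy^2
  Ixy <- sum(r^4 * sin(th) * cos(th)) * dth / 4 - A * cx * cy
  ev <- eigen(matrix(c(Ixx, Ixy, Ixy, Iyy) / A, 2L), symmetric = TRUE,
              only.values = TRUE)$values
  major <- 4 * sqrt(ev[1L]); minor <- 4 * sqrt(max(ev[2L], 0))
  # caliper sweep over 720 directions on a dense boundary polygon
  ang <- pi * (0:719) / 720
  proj <- cbind(x, y) %*% rbind(cos(ang), sin(ang))
  widths <- apply(proj, 2L, function(v) max(v) - min(v))
  data.frame(file = "analytic", pixel_size = NA_real_, area = A, perimeter = L,
             average_radius = r0,
             roundness = 4 * A / (pi * major^2),
             aspect_ratio = if (minor > 0) major / minor else Inf,
             feret = max(widths), min_feret = min(widths),
             circularity = 4 * pi * A / L^2,
             inflection_points = as.integer(infl),
             weighted_curvature = weighted, dne = dne,
             transparency = NA_real_, mean_curvature = mean_k,
             std_curvature = std_k, r0_std_curvature = std_k * r0,
             dne_r0 = dne * r0, stringsAsFactors = FALSE)
}

#' Rendering parameters for synthetic brightfield images
#'
#' Emulates an 8-bit brightfield frame of a single organoid: light
#' background, darker organoid whose dense core is darkest, and a more
#' transparent (textured) neuroepithelial rim. Intensity transitions are
#' blended over a few microns, as in defocused brightfield optics.
#'
#' @param pixel_size microns per pixel.
#' @param image_size square frame side in pixels.
#' @param background_level,rim_level,core_level 8-bit intensities
#'   (background > rim > core).
#' @param rim_fraction fraction of the local radius forming the rim.
#' @param texture_amp amplitude (intensity sd) of the band-limited rim
#'   texture.
#' @param texture_scale correlation length of the texture (pixels).
#' @param photon_noise_sd global Gaussian intensity noise.
#' @param blend_um width of the core-to-rim intensity blend (microns); wide
#'   enough that the blend itself carries negligible Laplacian response.
#' @param quantize clamp and round to 8-bit as the final step. Disable to
#'   test intensity-linearity properties free of quantization noise.
#' @export
render_spec <- function(pixel_size = 6, image_size = 384L,
                        background_level = 220, rim_level = 150,
                        core_level = 90, rim_fraction = 0.35,
                        texture_amp = 12, texture_scale = 3,
                        photon_noise_sd = 4, blend_um = 60,
                        quantize = TRUE) {
  if (!(background_level > rim_level && rim_level > core_level))
    ms_validation("levels must satisfy background > rim > core (dark organoid on a light field)")
  structure(list(pixel_size = pixel_size, image_size = as.integer(image_size),
                 background_level = background_level, rim_level = rim_level,
                 core_level = core_level, rim_fraction = rim_fraction,
                 texture_amp = texture_amp, texture_scale = texture_scale,
                 photon_noise_sd = photon_noise_sd, blend_um = blend_um,
                 quantize = isTRUE(quantize)),
            class = "render_spec")
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Render a shape spec as a brightfield-style image
#'
#' Rasterizes the polar shape onto a calibrated 8-bit frame together with
#' its ground-truth mask. The shape must fit with at least a 5% margin.
#'
#' @param spec a [shape_spec()].
#' @param render a [render_spec()].
#' @param seed RNG seed for texture and photon noise.
#' @return list with `image` ([calibrated_image()]), `mask`
#'   ([binary_mask()] ground truth) and `spec`.
#' @export
render_shape_image <- function(spec, render = render_spec(), seed = NULL) {
  S <- render$image_size
  ps <- render$pixel_size
  ctr <- (S - 1) / 2
  xs <- ((0:(S - 1)) - ctr) * ps
  # y-up frame: row 1 (top) has the largest y
  ys <- (ctr - (0:(S - 1))) * ps
  gx <- matrix(xs, S, S, byrow = TRUE)
  gy <- matrix(ys, S, S)
  rho <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx)
  rtheta <- matrix(spec_radius(spec, as.vector(theta)), S, S)
  if (max(rtheta) > (S / 2 - 0.05 * S) * ps)
    ms_validation("shape exceeds the frame margin; reduce base_radius or pixel_size")
  mask <- rho <= rtheta
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  core_edge <- (1 - render$rim_fraction) * rtheta
  s_rim <- smoothstep((rho - core_edge) / render$blend_um)       # 0 core -> 1 rim
  s_bg <- smoothstep((rho - rtheta) / (2 * ps) + 0.5)            # 0 inside -> 1 outside
  level <- render$core_level + (render$rim_level - render$core_level) * s_rim
  level <- level + (render$background_level - level) * s_bg
  if (render$texture_amp > 0) {
    field <- matrix(stats::rnorm(S * S), S, S)
    field <- as.matrix(EBImage::gblur(field, sigma = render$texture_scale))
    field <- field / stats::sd(field)
    level <- level + render$texture_amp * field * s_rim * (1 - s_bg)
  }
  if (render$photon_noise_sd > 0)
    level <- level + stats::rnorm(S * S, 0, render$photon_noise_sd)
  if (render$quantize) {
    px <- round(pmin(pmax(level, 0), 255))
    img <- calibrated_image(px, ps, bit_depth = 8L, source = "synthetic")
  } else {
    img <- calibrated_image(pmin(pmax(level, 0), 255), ps, bit_depth = 32L,
                            source = "synthetic")
  }
  list(image = img, mask = binary_mask(mask, ps), spec = spec)
}

#' Default complexity profiles of the synthetic cohort
#'
#' "complex" emulates reference-grade organoids with 6-8 neural buds of
#' relative amplitude 0.2-0.3; "smooth" emulates poor-morphology organoids
#' with near-circular outlines (amplitude at most 0.05). Base radii are
#' log-normal around 450 microns (about 0.9 mm diameter, typical of
#' day-18 neural organoids) with 15% spread in both classes, so size does
#' not separate the classes by construction.
#'
#' @export
cohort_profiles <- function() {
  list(complex = list(lobes = 6:8, amplitude = c(0.2, 0.3), noise_amp = 0.01),
       smooth = list(lobes = 4:8, amplitude = c(0, 0.05), noise_amp = 0.01),
       base_radius_meanlog = log(450), base_radius_sdlog = 0.15)
}

#' Generate a synthetic reference + input cohort
#'
#' Seeded cohort of rendered brightfield-style images with known class
#' labels, emulating the pooling of input organoids with a curated
#' reference dataset: all reference organoids are "complex"; input
#' organoids split into complex and smooth classes.
#'
#' @param n_reference reference organoids (all complex).
#' @param n_input_complex,n_input_smooth input organoids per class.
#' @param seed cohort RNG seed.
#' @param profiles see [cohort_profiles()].
#' @param render a [render_spec()].
#' @param contours_only skip rasterization and return only shape contours
#'   (used for geometry-level validation).
#' @return list with `samples` (data.frame: id, role, class), `specs`, and
#'   unless `contours_only` also `images` and `masks` (lists indexed like
#'   `samples`).
#' @export
sample_cohort <- function(n_reference = 20L, n_input_complex = 3L,
                          n_input_smooth = 3L, seed = 1L,
                          profiles = cohort_profiles(),
                          render = render_spec(), contours_only = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  classes <- c(rep("complex", n_reference), rep("complex", n_input_complex),
               rep("smooth", n_input_smooth))
  roles <- c(rep("reference", n_reference),
             rep("input", n_input_complex + n_input_smooth))
  ids <- c(sprintf("ref-%02d", seq_len(n_reference)),
           sprintf("input-complex-%d", seq_len(n_input_complex)),
           sprintf("input-smooth-%d", seq_len(n_input_smooth)))
  n <- length(ids)
  specs <- vector("list", n)
  seeds <- sample.int(2^30, 2L * n)
  for (i in seq_len(n)) {
    pr <- profiles[[classes[i]]]
    # truncated at 2.5 sigma: extreme sizes are culled at imaging time anyway,
    # and every shape must fit the rendering frame
    z <- max(min(stats::rnorm(1), 2.5), -2.5)
    R <- exp(profiles$base_radius_meanlog + profiles$base_radius_sdlog * z)
    lob <- data.frame(order = sample(pr$lobes, 1L),
                      amplitude = stats::runif(1, pr$amplitude[1L], pr$amplitude[2L]),
                      phase = stats::runif(1, 0, 2 * pi))
    specs[[i]] <- shape_spec(R, lobes = lob, noise_amp = pr$noise_amp,
                             seed = seeds[i])
  }
  out <- list(samples = data.frame(id = ids, role = roles, class = classes,
                                   stringsAsFactors = FALSE),
              specs = specs, seed = seed)
  if (!contours_only) {
    rendered <- lapply(seq_len(n), function(i)
      render_shape_image(specs[[i]], render, seed = seeds[n + i]))
    out$images <- lapply(rendered, `[[`, "image")
    out$masks <- lapply(rendered, `[[`, "mask")
  }
  out
}
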