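test_that("area and perimeter match closed forms on circle and square", {
  ap <- polygon_area_perimeter(make_circle(100))
  expect_equal(ap[["area"]], pi * 100^2, tolerance = 1e-3)
  expect_equal(ap[["perimeter"]], 2 * pi * 100, tolerance = 1e-3)

  ap2 <- polygon_area_perimeter(make_square(100, 32L))
  expect_equal(ap2[["area"]], 10000)
  expect_equal(ap2[["perimeter"]], 400)

  expect_error(polygon_area_perimeter(
    as_contour(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10)), normalize = FALSE),
    check = TRUE), class = "morphoscreen_validation")
})

test_that("rotating-calipers Feret equals brute force on random polygons", {
  expect_equal(unname(feret_diameters(make_circle(100))), c(200, 200), tolerance = 0.005)

  fer <- feret_diameters(make_square(100, 16L))
  expect_equal(fer[["feret"]], 100 * sqrt(2), tolerance = 1e-9)
  expect_equal(fer[["min_feret"]], 100, tolerance = 1e-9)

  set.seed(19)
  for (i in 1:20) {
    th <- sort(runif(50, 0, 2 * pi))
    r <- runif(50, 20, 100)
    p <- as_contour(cbind(r * cos(th), r * sin(th)))
    fast <- feret_diameters(p)
    brute_max <- max(stats::dist(unclass(p)))
    expect_equal(fast[["feret"]], brute_max, tolerance = 1e-12)
    # min width oracle: fine sweep over directions
    ang <- pi * (0:3599) / 3600
    proj <- unclass(p) %*% rbind(cos(ang), sin(ang))
    brute_min <- min(apply(proj, 2, function(v) max(v) - min(v)))
    # the sweep minimum sits at a width-function kink, so its grid error is
    # first order in the angular step
    expect_lte(fast[["min_feret"]], brute_min + 1e-9)
    expect_equal(fast[["min_feret"]], brute_min, tolerance = 2e-3)
    expect_gte(fast[["feret"]], fast[["min_feret"]])
  }
})

test_that("equivalent-ellipse shape factors: circle, 2:1 ellipse, rotation invariance", {
  e1 <- ellipse_shape_factors(make_circle(100))
  expect_equal(e1[["major_axis"]], 200, tolerance = 1e-3)
  expect_equal(e1[["roundness"]], 1, tolerance = 0.01)
  expect_equal(e1[["aspect_ratio"]], 1, tolerance = 1e-3)

  e2 <- ellipse_shape_factors(make_ellipse(200, 100))
  expect_equal(e2[["roundness"]], 0.5, tolerance = 1e-3)
  expect_equal(e2[["aspect_ratio"]], 2, tolerance = 1e-3)

  a <- 37 * pi / 180
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
  rot <- as_contour(unclass(make_ellipse(200, 100)) %*% t(Rm))
  e3 <- ellipse_shape_factors(rot)
  expect_equal(e3[["roundness"]], e2[["roundness"]], tolerance = 1e-6)
  expect_equal(e3[["aspect_ratio"]], e2[["aspect_ratio"]], tolerance = 1e-6)
})

test_that("circularity: circle 1, square pi/4, strictly decreasing in lobe amplitude", {
  ap <- polygon_area_perimeter(make_circle(100))
  expect_equal(circularity(ap[["area"]], ap[["perimeter"]]), 1, tolerance = 0.002)
  expect_equal(circularity(10000, 400), pi / 4, tolerance = 1e-12)

  circs <- sapply(seq(0.05, 0.35, by = 0.05), function(a) {
    sp <- shape_spec(100, lobes = data.frame(order = 6, amplitude = a, phase = 0))
    measure_exact(shape_contour(sp, 1024L), 1024L)$circularity
  })
  expect_true(all(diff(circs) < 0))
  expect_lt(circs[1], 1)
})

test_that("transparency is zero for constants, offset invariant and contrast linear", {
  S <- 96
  mk <- binary_mask(matrix(TRUE, S, S), 1)
  flat <- calibrated_image(matrix(128, S, S), 1)
  expect_lt(transparency(flat, mk), 1e-10)

  tex <- 10 * sin(outer(1:S, 1:S, function(i, j) i / 2 + j / 3))
  base <- matrix(128, S, S)
  t1 <- transparency(calibrated_image(base + tex, 1), mk)
  t_off <- transparency(calibrated_image(base + tex + 40, 1), mk)
  t_2x <- transparency(calibrated_image(base + 2 * tex, 1), mk)
  expect_equal(t_off, t1, tolerance = 1e-9)
  expect_equal(t_2x / t1, 2, tolerance = 0.05)

  expect_error(transparency(flat, binary_mask(matrix(FALSE, S, S), 1)),
               class = "morphoscreen_validation")
})

test_that("measured records satisfy the morphometric invariants over random shapes", {
  set.seed(29)
  for (i in 1:40) {
    n <- sample(1:8, 1); a <- runif(1, 0, 0.35)
    sp <- shape_spec(runif(1, 150, 600),
                     lobes = data.frame(order = n, amplitude = a,
                                        phase = runif(1, 0, 2 * pi)),
                     noise_amp = runif(1, 0, 0.015), seed = i)
    m <- measure_organoid(shape_contour(sp, 1024L),
                          config = geometry_config(n_samples = 1024L))
    expect_gt(m$area, 0)
    expect_gt(m$perimeter, 0)
    expect_gte(m$feret, m$min_feret)
    expect_gte(m$aspect_ratio, 1)
    expect_lte(m$circularity, 1.01)
    expect_lte(m$roundness, 1.01)
    expect_gte(m$inflection_points, 0L)
    expect_identical(m$inflection_points %% 2L, 0L)
    expect_equal(m$dne_r0, m$dne * m$average_radius)
    expect_equal(m$r0_std_curvature, m$std_curvature * m$average_radius)
  }
})

test_that("a measured synthetic circle image behaves like a circle", {
  sp <- shape_spec(420, seed = 3)
  r <- render_shape_image(sp, render_spec(), seed = 11)
  # ground-truth mask: isolates the raster-measurement path from the
  # (separately tested) segmentation wobble induced by rim texture
  m <- measure_organoid(mask_to_contour(r$mask), image = r$image, mask = r$mask,
                        file = "circle")
  expect_equal(m$circularity, 1, tolerance = 0.02)
  expect_equal(m$roundness, 1, tolerance = 0.02)
  expect_identical(m$inflection_points, 0L)
  expect_equal(m$feret / m$min_feret, 1, tolerance = 0.01)
  expect_equal(m$pixel_size, 6)
  expect_false(is.na(m$transparency))

  seg <- measure_organoid(mask_to_contour(auto_segment(r$image)),
                          image = r$image, file = "circle-auto")
  expect_equal(seg$circularity, 1, tolerance = 0.02)
  expect_equal(seg$feret / seg$min_feret, 1, tolerance = 0.03)
})
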