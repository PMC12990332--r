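test_that("uniform arclength resampling preserves geometry and is idempotent", {
  sq <- make_square(100, 64L)
  rs <- resample_closed_contour(sq, 400L)
  expect_equal(nrow(rs), 400L)
  el <- sqrt(rowSums((unclass(rs) - unclass(rs)[c(2:400, 1), ])^2))
  expect_lt(stats::sd(el) / mean(el), 0.01)              # 1 um spacing, uniform
  expect_equal(mean(el), 1, tolerance = 0.01)
  expect_equal(sum(el), 400, tolerance = 0.005)          # perimeter preserved

  circ <- make_circle(100, 512L)
  rs2 <- resample_closed_contour(circ, 1024L)
  radii <- sqrt(rowSums(unclass(rs2)^2))
  expect_lt(diff(range(radii)) / 100, 1e-3)

  again <- resample_closed_contour(rs2, 1024L)
  expect_lt(max(abs(unclass(again) - unclass(rs2))), 1e-6)

  expect_error(resample_closed_contour(circ, 8L), class = "morphoscreen_validation")
})

test_that("periodic Gaussian smoothing is identity at sigma 0 and kills high-frequency zigzag", {
  circ <- make_circle(100, 1024L)
  expect_identical(smooth_closed_contour(circ, 0), circ)

  sm <- smooth_closed_contour(circ, 5)
  # circle stays a circle (slightly smaller), curvature still constant
  dv <- contour_derivatives(resample_closed_contour(sm, 1024L))
  k <- curvature_profile(dv)$kappa
  expect_lt(stats::sd(k) / mean(k), 1e-3)
  expect_lt(abs(mean(colMeans(unclass(sm))) - mean(colMeans(unclass(circ)))), 1e-6)

  # zigzag of ~10 um wavelength on a circle
  th <- 2 * pi * (0:2047) / 2048
  r <- 100 + 2 * cos(64 * th)
  zig <- as_contour(cbind(r * cos(th), r * sin(th)))
  count_infl <- function(ct, sigma) {
    cc <- resample_closed_contour(ct, 2048L)
    if (sigma > 0) cc <- resample_closed_contour(smooth_closed_contour(cc, sigma), 2048L)
    dv <- contour_derivatives(cc)
    count_inflection_points(curvature_profile(dv), min_arc_um = 0.5)
  }
  expect_gt(count_infl(zig, 0), 0)
  expect_identical(count_infl(zig, 12), 0L)
})

test_that("derivatives are unit speed and recover the Frenet relations on a circle", {
  cc <- resample_closed_contour(make_circle(100, 4096L), 1024L)
  dv <- contour_derivatives(cc)
  expect_true(all(dv$dx^2 + dv$dy^2 > 0.999 & dv$dx^2 + dv$dy^2 < 1.001))
  expect_equal(sqrt(dv$dxx^2 + dv$dyy^2), rep(0.01, 1024L), tolerance = 0.01)

  # non-uniform sampling is rejected with advice to resample
  th <- 2 * pi * ((0:1023) / 1024)^2
  bad <- as_contour(cbind(100 * cos(th), 100 * sin(th)))
  expect_error(contour_derivatives(bad), class = "morphoscreen_validation")
})

test_that("signed curvature matches closed forms and flips with orientation", {
  cc <- resample_closed_contour(make_circle(100, 4096L), 1024L)
  k <- curvature_profile(contour_derivatives(cc))$kappa
  expect_equal(k, rep(0.01, 1024L), tolerance = 0.01)

  ce <- resample_closed_contour(make_ellipse(200, 100, 8192L), 2048L)
  ke <- curvature_profile(contour_derivatives(ce))$kappa
  expect_equal(max(ke), 200 / 100^2, tolerance = 0.02)
  expect_equal(min(ke), 100 / 200^2, tolerance = 0.02)

  # clockwise circle: negate order without renormalizing
  p <- unclass(cc)
  cw <- structure(p[nrow(p):1, ], class = c("contour", "matrix"))
  kcw <- curvature_profile(contour_derivatives(cw))$kappa
  expect_equal(kcw, rep(-0.01, 1024L), tolerance = 0.01)

  # zero tangent is a classed numerical-degeneracy error naming the index
  dv0 <- structure(list(dx = c(0, 1), dy = c(0, 0), dxx = c(0, 0), dyy = c(0, 0),
                        seg_len = c(1, 1)), class = "derivative_set")
  expect_error(curvature_profile(dv0), "index 1", class = "morphoscreen_validation")
})

test_that("curvature summaries: turning number 2*pi, circle statistics, ellipse spread", {
  cc <- resample_closed_contour(make_circle(100, 4096L), 1024L)
  dv <- contour_derivatives(cc)
  cs <- curvature_summaries(curvature_profile(dv), dv)
  expect_equal(cs[["mean_curvature"]], 0.01, tolerance = 1e-3)
  expect_lt(cs[["std_curvature"]], 1e-4)
  expect_equal(cs[["weighted_curvature"]], 2 * pi, tolerance = 1e-3)

  # 6-lobed rosette keeps total turning 2*pi despite concavities
  sp <- shape_spec(100, lobes = data.frame(order = 6, amplitude = 0.25, phase = 0))
  m <- measure_exact(shape_contour(sp, 2048L))
  expect_equal(m$weighted_curvature, 2 * pi, tolerance = 0.01)

  ce <- resample_closed_contour(make_ellipse(200, 100, 8192L), 2048L)
  dve <- contour_derivatives(ce)
  cse <- curvature_summaries(curvature_profile(dve), dve)
  expect_gt(cse[["std_curvature"]], 0)
  # arclength-mean curvature of any convex closed curve is 2*pi / perimeter
  expect_equal(cse[["mean_curvature"]], 2 * pi / sum(dve$seg_len),
               tolerance = 1e-3)
})

test_that("inflection counting: 0 for convex shapes, 2n for n-lobed rosettes, even always", {
  for (ct in list(make_circle(100), make_ellipse(200, 100))) {
    m <- measure_exact(ct)
    expect_identical(m$inflection_points, 0L)
  }
  sp <- shape_spec(100, lobes = data.frame(order = 6, amplitude = 0.25, phase = 1))
  expect_identical(measure_exact(shape_contour(sp, 2048L))$inflection_points, 12L)

  # degenerate all-zero profile
  pr0 <- structure(list(kappa = rep(0, 64), arc_pos = seq(0, 63)),
                   class = "curvature_profile")
  r <- count_inflection_points(pr0, 1)
  expect_identical(as.integer(r), 0L)
  expect_true(attr(r, "degenerate"))
})

test_that("DNE matches ln(2*pi/R) for circles, grows with lobes, shifts by -ln(c) under scaling", {
  cc <- make_circle(100, 2048L)
  m <- measure_exact(cc)
  expect_equal(m$dne, log(2 * pi / 100), tolerance = 0.005)

  sp <- shape_spec(100, lobes = data.frame(order = 6, amplitude = 0.25, phase = 0))
  mr <- measure_exact(shape_contour(sp, 2048L))
  expect_gt(mr$dne, m$dne)

  # scale covariance across random shapes: DNE(c * shape) = DNE - ln c,
  # R0 scales by c, kappa statistics by 1/c
  set.seed(71)
  for (i in 1:5) {
    n <- sample(2:8, 1); a <- runif(1, 0.05, 0.3); cfac <- runif(1, 1.5, 4)
    s1 <- shape_spec(150, lobes = data.frame(order = n, amplitude = a, phase = 0))
    s2 <- shape_spec(150 * cfac, lobes = data.frame(order = n, amplitude = a, phase = 0))
    m1 <- measure_exact(shape_contour(s1, 1024L), 1024L)
    m2 <- measure_exact(shape_contour(s2, 1024L), 1024L)
    expect_equal(m2$dne, m1$dne - log(cfac), tolerance = 1e-3)
    expect_equal(m2$average_radius / m1$average_radius, cfac, tolerance = 1e-3)
    expect_equal(m2$std_curvature / m1$std_curvature, 1 / cfac, tolerance = 1e-2)
    expect_equal(m2$circularity, m1$circularity, tolerance = 1e-3)
  }

  # flat profile guard
  dvf <- structure(list(dx = rep(1, 8), dy = rep(0, 8), dxx = rep(0, 8),
                        dyy = rep(0, 8), seg_len = rep(1, 8)),
                   class = "derivative_set")
  prf <- structure(list(kappa = rep(0, 8), arc_pos = 0:7), class = "curvature_profile")
  d <- dirichlet_normal_energy(prf, dvf)
  expect_true(attr(d, "degenerate"))
})

test_that("average radius: circle R, square matches the edge integral, translation invariant", {
  expect_equal(average_radius(make_circle(100)), 100, tolerance = 1e-3)
  # mean centroid-to-boundary distance of a square, by direct integration:
  # per half-edge, mean of sqrt(t^2 + (s/2)^2) for t in [0, s/2]
  s <- 100
  oracle <- stats::integrate(function(t) sqrt(t^2 + (s / 2)^2), 0, s / 2)$value / (s / 2)
  expect_equal(average_radius(make_square(s, 128L)), oracle, tolerance = 1e-3)

  sq <- make_square(100, 64L)
  moved <- as_contour(unclass(sq) + matrix(c(1000, -500), nrow(sq), 2, byrow = TRUE))
  expect_equal(average_radius(moved), average_radius(sq), tolerance = 1e-9)
})

test_that("reversing orientation negates curvature pointwise but preserves counts and energy", {
  sp <- shape_spec(120, lobes = data.frame(order = 5, amplitude = 0.22, phase = 0.4))
  cc <- resample_closed_contour(shape_contour(sp, 1024L), 1024L)
  p <- unclass(cc)
  rev_cc <- structure(p[nrow(p):1, ], class = c("contour", "matrix"))
  dv1 <- contour_derivatives(cc); pr1 <- curvature_profile(dv1)
  dv2 <- contour_derivatives(rev_cc); pr2 <- curvature_profile(dv2)
  expect_lt(max(abs(pr2$kappa + rev(pr1$kappa))), 1e-6)
  L <- sum(dv1$seg_len)
  expect_identical(count_inflection_points(pr2, 0.02 * L),
                   count_inflection_points(pr1, 0.02 * L))
  expect_equal(dirichlet_normal_energy(pr2, dv2), dirichlet_normal_energy(pr1, dv1),
               tolerance = 1e-6)
})

test_that("rigid motions leave all geometry descriptors unchanged", {
  sp <- shape_spec(200, lobes = data.frame(order = 7, amplitude = 0.28, phase = 0.9))
  ct <- shape_contour(sp, 1024L)
  a <- 37 * pi / 180
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
  moved <- as_contour(unclass(ct) %*% t(Rm) + matrix(c(312, -77), nrow(ct), 2, byrow = TRUE))
  m1 <- measure_exact(ct, 1024L)
  m2 <- measure_exact(moved, 1024L)
  for (f in c("area", "perimeter", "average_radius", "roundness", "aspect_ratio",
              "feret", "min_feret", "circularity", "dne", "std_curvature"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-6)
  expect_identical(m2$inflection_points, m1$inflection_points)
})
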