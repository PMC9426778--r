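test_that("hue_centroid computes luma-weighted centroids and flags missing frames", {
  # single in-window pixel at (col 10, row 20)
  hue <- matrix(0, 30, 30); luma <- matrix(1, 30, 30)
  hue[20, 10] <- 120
  expect_equal(unname(hue_centroid(hue, luma, c(100, 140))), c(10, 20))
  # two in-window pixels, luma 1 and 3 -> weighted mean x
  hue2 <- matrix(0, 3, 12); luma2 <- matrix(0, 3, 12)
  hue2[1, 1] <- 120; hue2[1, 11] <- 120
  luma2[1, 1] <- 1; luma2[1, 11] <- 3
  expect_equal(unname(hue_centroid(hue2, luma2, c(100, 140))),
               c((1 * 1 + 11 * 3) / 4, 1))
  # no in-window pixels -> missing, not an error
  expect_true(all(is.na(hue_centroid(hue2, luma2, c(200, 210)))))
  # below min_pixels -> missing
  expect_true(all(is.na(hue_centroid(hue2, luma2, c(100, 140), min_pixels = 3))))
  # wraparound hue window
  hue3 <- matrix(c(350, 5, 90, 90), 2, 2); luma3 <- matrix(1, 2, 2)
  expect_false(any(is.na(hue_centroid(hue3, luma3, c(340, 10)))))
  expect_error(hue_centroid(matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0),
                            c(0, 1)), class = "whiskeye_fit_error")
})

test_that("fit_circle is exact on circles and errors on degenerate input", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  f <- fit_circle(cbind(5 + 3 * cos(th), 5 + 3 * sin(th)))
  expect_equal(unname(f$center), c(5, 5), tolerance = 1e-10)
  expect_equal(f$radius, 3, tolerance = 1e-10)
  expect_equal(f$residual, 0, tolerance = 1e-10)
  # three points: exact circumscribed circle (closed-form oracle)
  set.seed(5)
  for (i in 1:10) {
    p <- matrix(rnorm(6, sd = 4), 3, 2)
    o <- oracle_circumcircle(p[1, ], p[2, ], p[3, ])
    f3 <- fit_circle(p)
    expect_equal(unname(f3$center), o$center, tolerance = 1e-6)
    expect_equal(f3$radius, o$radius, tolerance = 1e-6)
  }
  expect_error(fit_circle(cbind(1:5, 2 * (1:5) + 1)), class = "whiskeye_fit_error")
  expect_error(fit_circle(cbind(1:2, 1:2)), class = "whiskeye_fit_error")
})

test_that("to_polar_angle follows the atan2 convention", {
  f <- fit_circle(cbind(2 + 3 * cos(seq(0, 5)), 1 + 3 * sin(seq(0, 5))))
  expect_equal(to_polar_angle(f$center + c(3, 0), f), 0, tolerance = 1e-8)
  expect_equal(to_polar_angle(f$center + c(0, 3), f), 90, tolerance = 1e-8)
  set.seed(6)
  p <- cbind(rnorm(20), rnorm(20))
  expect_equal(to_polar_angle(p, f),
               atan2(p[, 2] - f$center[2], p[, 1] - f$center[1]) * 180 / pi)
})

test_that("fit_ellipse recovers known ellipses and rejects degenerate input", {
  # axis-aligned ellipse center (3,4), semi-axes (2,1)
  f <- fit_ellipse(ellipse_points(3, 4, 2, 1))
  expect_equal(unname(f$center), c(3, 4), tolerance = 1e-8)
  expect_equal(unname(f$semi_axes), c(2, 1), tolerance = 1e-8)
  expect_equal(f$residual, 0, tolerance = 1e-8)
  expect_equal(unname(f$diameter["equivalent"]), 2 * sqrt(2), tolerance = 1e-8)
  # rotated ellipse
  f2 <- fit_ellipse(ellipse_points(-1, 2, 3, 1.5, theta = 0.7))
  expect_equal(unname(f2$center), c(-1, 2), tolerance = 1e-8)
  expect_equal(unname(f2$semi_axes), c(3, 1.5), tolerance = 1e-8)
  expect_equal(abs(cos(f2$orientation - 0.7)), 1, tolerance = 1e-6)
  # circle -> equal semi-axes
  f3 <- fit_ellipse(ellipse_points(0, 0, 2, 2))
  expect_equal(unname(f3$semi_axes[1]), unname(f3$semi_axes[2]), tolerance = 1e-8)
  # residual is nonzero iff points leave the curve
  pts <- ellipse_points(3, 4, 2, 1)
  pts[1, ] <- pts[1, ] + 0.3
  expect_gt(fit_ellipse(pts)$residual, 1e-3)
  # collinear and insufficient points
  expect_error(fit_ellipse(cbind(1:8, 2 * (1:8))), class = "whiskeye_fit_error")
  expect_error(fit_ellipse(ellipse_points(0, 0, 2, 1)[1:4, ]),
               class = "whiskeye_fit_error")
})

test_that("fit_eye_geometry computes corners as parabola crossings", {
  xs <- seq(-2, 2, by = 0.25)
  top <- cbind(xs, -xs^2 + 2)
  bottom <- cbind(xs, xs^2)
  g <- fit_eye_geometry(top, bottom)
  expect_equal(unname(g$corners["nasal", ]), c(-1, 1), tolerance = 1e-9)
  expect_equal(unname(g$corners["temporal", ]), c(1, 1), tolerance = 1e-9)
  expect_equal(g$width, 2, tolerance = 1e-9)
  # nasal side assignment from metadata
  g2 <- fit_eye_geometry(top, bottom, nasal_x = "max")
  expect_equal(unname(g2$corners["nasal", 1]), 1)
  # non-crossing parabolas and coincident parabolas are geometry errors
  expect_error(fit_eye_geometry(cbind(xs, xs^2 + 1), bottom),
               class = "whiskeye_geometry_error")
  expect_error(fit_eye_geometry(bottom, bottom), class = "whiskeye_geometry_error")
  # noisy points: corners within 0.05 of the analytic intersections
  set.seed(8)
  for (i in 1:5) {
    gN <- fit_eye_geometry(top + rnorm(length(top), 0, 0.01),
                           bottom + rnorm(length(bottom), 0, 0.01))
    expect_lt(max(abs(gN$corners - g$corners)), 0.05)
  }
})

test_that("normalize_pupil projects onto the eye-width segment", {
  g <- structure(list(corners = rbind(nasal = c(x = 0, y = 0),
                                      temporal = c(x = 10, y = 0)), width = 10),
                 class = "eye_geometry")
  expect_equal(normalize_pupil(c(3, 2), g), 0.3)    # perpendicular offset ignored
  expect_equal(normalize_pupil(c(0, 0), g), 0)      # nasal corner
  expect_equal(normalize_pupil(c(10, 0), g), 1)     # temporal corner
  expect_equal(normalize_pupil(c(5, 4), g), 0.5)    # midpoint + perpendicular
  expect_equal(normalize_pupil(c(13, 0), g), 1.3)   # not clamped
})

test_that("fits are equivariant under similarity transforms", {
  set.seed(9)
  rot <- function(p, th, t, s) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sweep(s * p %*% t(R), 2, -t)
  }
  th <- 0.6; t <- c(3, -2); s <- 1.7
  pts <- ellipse_points(1, 2, 2, 1, theta = 0.3)
  f0 <- fit_ellipse(pts); f1 <- fit_ellipse(rot(pts, th, t, s))
  expect_equal(unname(f1$center), unname(as.vector(rot(rbind(f0$center), th, t, s))),
               tolerance = 1e-7)
  expect_equal(unname(f1$semi_axes), unname(s * f0$semi_axes), tolerance = 1e-7)
  circ <- cbind(4 + 2 * cos(seq(0, 5)), 4 + 2 * sin(seq(0, 5)))
  c0 <- fit_circle(circ); c1 <- fit_circle(rot(circ, th, t, s))
  expect_equal(unname(c1$center), unname(as.vector(rot(rbind(c0$center), th, t, s))),
               tolerance = 1e-8)
  expect_equal(c1$radius, s * c0$radius, tolerance = 1e-8)
})

test_that("fit_pupil_frames gates on confidence and drops thin frames", {
  mk <- function(frame, cx, like = rep(1, 8)) {
    pts <- ellipse_points(cx, 100, 15, 11, theta = 0.2)
    data.frame(frame = frame, bodypart = sprintf("pupil_%d", 1:8),
               x = pts[, 1], y = pts[, 2], likelihood = like)
  }
  kp <- rbind(mk(0, 80), mk(1, 90, like = c(rep(0.2, 4), rep(1, 4))), mk(2, 100))
  g <- structure(list(corners = rbind(nasal = c(x = 40, y = 100),
                                      temporal = c(x = 152, y = 100)),
                      width = 112), class = "eye_geometry")
  out <- fit_pupil_frames(kp, g)
  expect_equal(out$x[out$frame == 0], 80, tolerance = 1e-8)
  expect_equal(out$normalized[out$frame == 2], (100 - 40) / 112, tolerance = 1e-8)
  # frame 1: only 4 confident points -> dropped as missing
  expect_true(is.na(out$x[out$frame == 1]))
  expect_equal(out$n_points[out$frame == 1], 4L)
  # lowering the confidence bar restores it
  out2 <- fit_pupil_frames(kp, g, min_confidence = 0.1)
  expect_equal(out2$x[out2$frame == 1], 90, tolerance = 1e-8)
})
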