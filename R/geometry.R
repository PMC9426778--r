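# Geometric fits that turn raw tracked points into analysis-ready variables:
# hue-masked centroids and a session circle fit for whiskers; per-frame
# ellipse fits, eyelid parabolas, eye corners and width-segment projection
# for the pupils.

as_points <- function(points, min_n, what) {
  p <- as.matrix(points)
  if (!is.numeric(p) || ncol(p) != 2L)
    fit_error(sprintf("%s: points must be an n x 2 numeric matrix", what))
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) < min_n)
    fit_error(sprintf("%s: need >= %d finite points, got %d", what, min_n, nrow(p)))
  p
}

#' Luma-weighted hue-masked centroid
#'
#' Collects the pixels whose hue falls inside a window and returns their
#' luma (brightness) weighted mean position, the primitive used to track a
#' painted whisker in a single video frame.
#'
#' @param hue Numeric matrix of per-pixel hue values (rows = y, cols = x).
#' @param luma Numeric matrix of per-pixel luma, same dimensions.
#' @param hue_window Length-2 numeric `(lo, hi)`; if `lo > hi` the window
#'   wraps around the hue circle.
#' @param min_pixels Minimum number of in-window pixels; below this the frame
#'   is reported missing (`c(NA, NA)`) so it can be filled by interpolation.
#' @return Numeric `c(x, y)` in pixel coordinates (x = column, y = row,
#'   1-based), or `c(NA, NA)` if fewer than `min_pixels` matched.
#' @export
hue_centroid <- function(hue, luma, hue_window, min_pixels = 1L) {
  if (length(hue) == 0L) fit_error("hue_centroid: empty image")
  if (!all(dim(hue) == dim(luma)))
    fit_error("hue_centroid: hue and luma dimensions differ")
  lo <- hue_window[1]; hi <- hue_window[2]
  mask <- if (lo <= hi) hue >= lo & hue <= hi else hue >= lo | hue <= hi
  mask[is.na(mask)] <- FALSE
  if (sum(mask) < min_pixels) return(c(x = NA_real_, y = NA_real_))
  w <- luma[mask]
  if (sum(w) <= 0) return(c(x = NA_real_, y = NA_real_))
  idx <- which(mask, arr.ind = TRUE)
  c(x = sum(idx[, 2] * w) / sum(w), y = sum(idx[, 1] * w) / sum(w))
}

#' Algebraic least-squares circle fit
#'
#' Kasa-type fit: linear least squares on `x^2 + y^2 = 2 a x + 2 b y + c`.
#' Exact on noiseless circular data; errors on collinear/degenerate input.
#'
#' @param points n x 2 matrix, n >= 3, not all collinear.
#' @return Object of class `circle_fit`: `center` (x, y), `radius`,
#'   `residual` (RMS radial distance).
#' @export
fit_circle <- function(points) {
  p <- as_points(points, 3L, "fit_circle")
  A <- cbind(2 * p[, 1], 2 * p[, 2], 1)
  b <- p[, 1]^2 + p[, 2]^2
  qrA <- qr(A)
  if (qrA$rank < 3L) fit_error("fit_circle: degenerate (collinear) points")
  sol <- qr.coef(qrA, b)
  center <- c(x = sol[[1]], y = sol[[2]])
  r2 <- sol[[3]] + sol[[1]]^2 + sol[[2]]^2
  if (!is.finite(r2) || r2 <= 0) fit_error("fit_circle: degenerate fit")
  radius <- sqrt(r2)
  d <- sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2)
  structure(list(center = center, radius = radius,
                 residual = sqrt(mean((d - radius)^2))),
            class = "circle_fit")
}

#' Polar angle about a fitted circle
#'
#' @param position n x 2 matrix (or length-2 vector) of positions.
#' @param fit A `circle_fit`.
#' @return Angle(s) in degrees in (-180, 180], measured counter-clockwise
#'   from the positive x axis about the circle center. The mapping of
#'   increasing angle to protraction is fixed downstream per side.
#' @export
to_polar_angle <- function(position, fit) {
  stopifnot(inherits(fit, "circle_fit"))
  p <- if (is.null(dim(position))) matrix(position, ncol = 2) else as.matrix(position)
  unname(atan2(p[, 2] - fit$center[2], p[, 1] - fit$center[1]) * 180 / pi)
}

#' Direct least-squares ellipse fit
#'
#' Fitzgibbon-style conic fit with the ellipse constraint `4ac - b^2 = 1`,
#' applied to centered/scaled coordinates for conditioning. Errors if fewer
#' than 5 points, if the configuration is degenerate, or if the best conic is
#' not an ellipse.
#'
#' @param points n x 2 matrix, n >= 5 (8 pupil-edge points in practice).
#' @return Object of class `ellipse_fit`: `center` (x, y), `semi_axes`
#'   (major, minor), `orientation` (radians, major axis vs x axis),
#'   `residual` (RMS approximate geometric distance), and `diameter`
#'   (named: major, minor, equivalent).
#' @export
fit_ellipse <- function(points) {
  p <- as_points(points, 5L, "fit_ellipse")
  mx <- mean(p[, 1]); my <- mean(p[, 2])
  sc <- max(stats::sd(p[, 1]), stats::sd(p[, 2]))
  if (!is.finite(sc) || sc <= 0) fit_error("fit_ellipse: degenerate points")
  x <- (p[, 1] - mx) / sc; y <- (p[, 2] - my) / sc

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  if (qr(S3)$rank < 3L || qr(cbind(D1, D2))$rank < 5L)
    fit_error("fit_ellipse: degenerate point configuration")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) fit_error("fit_ellipse: best-fit conic is not an ellipse")
  a1 <- V[, ok[1]]
  a2 <- as.vector(Tm %*% a1)
  co <- c(a1, a2)  # A B C D E F in scaled frame

  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; Fc <- co[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) fit_error("fit_ellipse: best-fit conic is not an ellipse")
  xc <- (2 * C * D - B * E) / den
  yc <- (2 * A * E - B * D) / den
  # semi-axes via the standard closed form
  num <- 2 * (A * E^2 + C * D^2 + Fc * B^2 - B * D * E - 4 * A * C * Fc)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + s)) / den
  ax2 <- -sqrt(num * (A + C - s)) / den
  if (!is.finite(ax1) || !is.finite(ax2) || ax1 <= 0 || ax2 <= 0)
    fit_error("fit_ellipse: degenerate ellipse")
  theta <- 0.5 * atan2(-B, C - A)
  semi <- sort(c(ax1, ax2), decreasing = TRUE)
  if (ax2 > ax1) theta <- theta + pi / 2
  theta <- atan2(sin(theta), cos(theta))

  # approximate geometric residual: |Q(x,y)| / |grad Q| in scaled frame
  Q <- A * x^2 + B * x * y + C * y^2 + D * x + E * y + Fc
  gx <- 2 * A * x + B * y + D
  gy <- B * x + 2 * C * y + E
  resid <- sqrt(mean((Q / pmax(sqrt(gx^2 + gy^2), 1e-12))^2)) * sc

  semi <- semi * sc
  structure(list(
    center = c(x = xc * sc + mx, y = yc * sc + my),
    semi_axes = c(major = semi[1], minor = semi[2]),
    orientation = theta,
    residual = resid,
    diameter = c(major = 2 * semi[1], minor = 2 * semi[2],
                 equivalent = 2 * sqrt(semi[1] * semi[2]))
  ), class = "ellipse_fit")
}

#' Least-squares parabola fit `y = a x^2 + b x + c`
#'
#' @param points n x 2 matrix with >= 3 distinct x values.
#' @return Numeric `c(a, b, c)`.
#' @export
fit_parabola <- function(points) {
  p <- as_points(points, 3L, "fit_parabola")
  if (length(unique(p[, 1])) < 3L)
    fit_error("fit_parabola: need >= 3 distinct x values")
  X <- cbind(p[, 1]^2, p[, 1], 1)
  sol <- qr.coef(qr(X), p[, 2])
  c(a = sol[[1]], b = sol[[2]], c = sol[[3]])
}

#' Eye geometry from eyelid point sets
#'
#' Fits one parabola to each eyelid, computes the two eye corners as the real
#' intersection points of the parabolas, and defines the eye-width segment
#' joining them. The nasal corner is assigned from side metadata so that
#' normalized pupil positions can be mapped into head-centered coordinates.
#'
#' @param top_points,bottom_points n x 2 matrices of eyelid outline points.
#' @param nasal_x `"min"` or `"max"`: whether the nasal corner is the one at
#'   smaller or larger image x for this eye's camera.
#' @return Object of class `eye_geometry`: `top`, `bottom` (parabola
#'   coefficients), `corners` (2 x 2 matrix, rows nasal/temporal), `width`.
#' @export
fit_eye_geometry <- function(top_points, bottom_points, nasal_x = c("min", "max")) {
  nasal_x <- match.arg(nasal_x)
  top <- fit_parabola(top_points)
  bottom <- fit_parabola(bottom_points)
  d <- top - bottom
  tol <- 1e-12
  if (all(abs(d) < tol)) geometry_error("eyelid parabolas are coincident")
  if (abs(d[1]) < tol) {
    geometry_error("eyelid parabolas do not form two corners (equal curvature)")
  }
  disc <- d[2]^2 - 4 * d[1] * d[3]
  if (disc <= 0) geometry_error("eyelid parabolas do not cross (no real corners)")
  roots <- sort(c((-d[2] + sqrt(disc)) / (2 * d[1]),
                  (-d[2] - sqrt(disc)) / (2 * d[1])))
  ys <- top[1] * roots^2 + top[2] * roots + top[3]
  corners <- cbind(x = roots, y = ys)
  if (nasal_x == "max") corners <- corners[2:1, , drop = FALSE]
  rownames(corners) <- c("nasal", "temporal")
  width <- sqrt(sum((corners[2, ] - corners[1, ])^2))
  if (width <= 0) geometry_error("zero eye width")
  structure(list(top = top, bottom = bottom, corners = corners, width = width),
            class = "eye_geometry")
}

#' Normalized pupil position
#'
#' Scalar projection of pupil center(s) onto the eye-width segment, expressed
#' as the fraction of the full eye width: 0 at the nasal corner, 1 at the
#' temporal corner, not clamped.
#'
#' @param position n x 2 matrix (or length-2 vector) of pupil centers.
#' @param geometry An `eye_geometry`.
#' @return Numeric vector of fractions.
#' @export
normalize_pupil <- function(position, geometry) {
  stopifnot(inherits(geometry, "eye_geometry"))
  p <- if (is.null(dim(position))) matrix(position, ncol = 2) else as.matrix(position)
  v <- geometry$corners[2, ] - geometry$corners[1, ]
  as.vector(((p[, 1] - geometry$corners[1, 1]) * v[1] +
             (p[, 2] - geometry$corners[1, 2]) * v[2]) / sum(v^2))
}

#' Per-frame pupil positions from edge keypoints with confidence gating
#'
#' Fits an ellipse to each frame's pupil-edge keypoints. Keypoints below
#' `min_confidence` are excluded; the frame is dropped (reported missing,
#' to be filled by downstream linear interpolation) if fewer than 5 usable
#' points remain or if the fit fails. Frames dropped here can never seed
#' saccade events.
#'
#' @param keypoints Long keypoint data.frame for one eye (`frame`,
#'   `bodypart`, `x`, `y`, `likelihood`) as returned by [read_keypoints()].
#' @param geometry Optional `eye_geometry`; when given, the normalized
#'   pupil position is included.
#' @param min_confidence Keypoint likelihood threshold.
#' @return data.frame: `frame`, `x`, `y`, `diameter` (equivalent),
#'   `normalized` (fraction of eye width or NA), `n_points`.
#' @export
fit_pupil_frames <- function(keypoints, geometry = NULL, min_confidence = 0.9) {
  kp <- as.data.frame(keypoints)
  frames <- sort(unique(kp$frame))
  out <- data.frame(frame = frames, x = NA_real_, y = NA_real_,
                    diameter = NA_real_, normalized = NA_real_,
                    n_points = 0L)
  like <- kp$likelihood
  like[is.na(like)] <- 1  # files without confidence keep all points
  for (i in seq_along(frames)) {
    sel <- kp$frame == frames[i] & like >= min_confidence &
      is.finite(kp$x) & is.finite(kp$y)
    out$n_points[i] <- sum(sel)
    if (out$n_points[i] < 5L) next
    fit <- tryCatch(fit_ellipse(cbind(kp$x[sel], kp$y[sel])),
                    whiskeye_fit_error = function(e) NULL)
    if (is.null(fit)) next
    out$x[i] <- fit$center[1]; out$y[i] <- fit$center[2]
    out$diameter[i] <- fit$diameter[["equivalent"]]
    if (!is.null(geometry))
      out$normalized[i] <- normalize_pupil(fit$center, geometry)
  }
  out
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("circle fit: center (%.3f, %.3f), r = %.3f, RMS residual %.3g\n",
              x$center[1], x$center[2], x$radius, x$residual))
  invisible(x)
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("ellipse fit: center (%.3f, %.3f), semi-axes (%.3f, %.3f), theta %.3f rad\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2], x$orientation))
  invisible(x)
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat(sprintf("eye geometry: corners (%.2f, %.2f) [nasal], (%.2f, %.2f) [temporal], width %.2f\n",
              x$corners[1, 1], x$corners[1, 2], x$corners[2, 1], x$corners[2, 2], x$width))
  invisible(x)
}
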