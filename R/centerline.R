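#' Centerline paths
#'
#' A `centerline_path` is an ordered polyline describing the medial axis of a
#' vessel, with cumulative arclength, unit tangents and curvature attached.
#' All coordinates and arclengths are in millimetres; curvature is 1/mm.
#'
#' @param points numeric matrix (n x 2 or n x 3) of ordered points, in mm.
#'   Two-column input is lifted to z = 0 (a venogram is a single planar
#'   projection, so its centerline lives in one plane).
#' @return an object of class `centerline_path`: a list with elements
#'   `points` (n x 3, mm), `s` (cumulative arclength, mm), `tangent`
#'   (n x 3 unit vectors) and `curvature` (1/mm).
#' @export
centerline_path <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) < 2L)
    stop("centerline needs at least two points")
  if (ncol(points) == 2L) points <- cbind(points, 0)
  if (ncol(points) != 3L) stop("points must have 2 or 3 columns")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    stop("duplicate consecutive points in centerline")
  s <- c(0, cumsum(seg))
  tang <- path_tangents(points, s)
  structure(list(points = points, s = s, tangent = tang$tangent,
                 curvature = tang$curvature),
            class = "centerline_path")
}

# central-difference unit tangents and curvature |dT/ds| for an ordered polyline
path_tangents <- function(points, s) {
  n <- nrow(points)
  tangent <- matrix(0, n, 3L)
  tangent[1L, ] <- points[2L, ] - points[1L, ]
  tangent[n, ] <- points[n, ] - points[n - 1L, ]
  if (n > 2L) {
    tangent[2:(n - 1L), ] <- points[3:n, ] - points[1:(n - 2L), ]
  }
  tangent <- tangent / sqrt(rowSums(tangent^2))
  curvature <- numeric(n)
  if (n > 2L) {
    i <- 2:(n - 1L)
    dT <- tangent[i + 1L, , drop = FALSE] - tangent[i - 1L, , drop = FALSE]
    ds <- s[i + 1L] - s[i - 1L]
    curvature[i] <- sqrt(rowSums(dT^2)) / ds
    curvature[1L] <- curvature[2L]
    curvature[n] <- curvature[n - 1L]
  }
  list(tangent = tangent, curvature = curvature)
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf("<centerline_path> %d points, arclength %.2f mm, max |kappa| %.4f /mm\n",
              nrow(x$points), max(x$s), max(abs(x$curvature))))
  invisible(x)
}

#' Total arclength of a centerline path (mm)
#' @param path a `centerline_path`
#' @export
path_length <- function(path) max(path$s)

#' Resample a centerline at uniform arclength spacing
#'
#' Linear interpolation of the polyline at uniform steps; tangents and
#' curvature are recomputed on the resampled points.
#'
#' @param path a `centerline_path`
#' @param spacing target arclength spacing in mm
#' @return a `centerline_path`
#' @export
resample_path <- function(path, spacing = 0.25) {
  stopifnot(spacing > 0)
  L <- path_length(path)
  s_new <- seq(0, L, by = spacing)
  if (s_new[length(s_new)] < L) s_new <- c(s_new, L)
  pts <- vapply(1:3, function(j) stats::approx(path$s, path$points[, j],
                                               xout = s_new)$y,
                numeric(length(s_new)))
  centerline_path(pts)
}

#' Smooth a centerline with a moving-average window
#'
#' Pixel-level skeletons give noisy second derivatives; a short arclength
#' moving average is applied before curvature estimation. Endpoints are kept
#' fixed and the window shrinks near them.
#'
#' @param path a `centerline_path`
#' @param window_mm full window width in mm (default 2)
#' @return a `centerline_path`
#' @export
smooth_path <- function(path, window_mm = 2) {
  n <- nrow(path$points)
  if (n < 5L || window_mm <= 0) return(path)
  ds <- mean(diff(path$s))
  half <- max(1L, round(window_mm / (2 * ds)))
  sm <- sapply(1:3, function(j) {
    x <- path$points[, j]
    out <- x
    for (i in seq_len(n)) {
      h <- min(half, i - 1L, n - i)
      out[i] <- mean(x[(i - h):(i + h)])
    }
    out
  })
  centerline_path(sm)
}

#' Measure the inscribed arch angle of a bent centerline
#'
#' Total-least-squares lines are fitted to the first and last
#' `straight_fraction` of the path's arclength (the straight pre- and
#' post-bend arms); the inscribed angle between their tangents at the
#' intersection is returned in degrees. A straight path gives 180 degrees;
#' smaller values mean a more acute bend.
#'
#' @param path a `centerline_path`
#' @param straight_fraction fraction of arclength at each end treated as the
#'   straight arm (default 0.25)
#' @return angle in degrees, in (0, 180]. If the fitted arm directions are
#'   parallel but the arms are not collinear, 180 is returned with attribute
#'   `parallel = TRUE` and a warning.
#' @export
measure_arch_angle <- function(path, straight_fraction = 0.25) {
  stopifnot(straight_fraction > 0, straight_fraction < 0.5)
  L <- path_length(path)
  i1 <- which(path$s <= straight_fraction * L)
  i2 <- which(path$s >= (1 - straight_fraction) * L)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("too few points in the straight arms to fit lines")
  d1 <- principal_direction(path$points[i1, , drop = FALSE])
  d2 <- principal_direction(path$points[i2, , drop = FALSE])
  # orient each direction along the direction of travel
  if (sum(d1 * (path$points[max(i1), ] - path$points[1L, ])) < 0) d1 <- -d1
  if (sum(d2 * (path$points[nrow(path$points), ] - path$points[min(i2), ])) < 0)
    d2 <- -d2
  cosd <- max(-1, min(1, sum(d1 * d2)))
  deflection <- acos(cosd) * 180 / pi
  angle <- 180 - deflection
  if (deflection < 1e-6) {
    # parallel arms: collinear path reads as straight; offset parallel arms
    # cannot intersect, flag it
    p1 <- colMeans(path$points[i1, , drop = FALSE])
    p2 <- colMeans(path$points[i2, , drop = FALSE])
    off <- (p2 - p1) - sum((p2 - p1) * d1) * d1
    if (sqrt(sum(off^2)) > 1e-6 * L) {
      warning("fitted arm directions are parallel but not collinear")
      return(structure(180, parallel = TRUE))
    }
  }
  angle
}

# first principal component direction of a point cloud (total least squares)
principal_direction <- function(pts) {
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  d <- pc$rotation[, 1L]
  d / sqrt(sum(d^2))
}
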