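#' Parametric specification of a cephalic-arch-like vessel
#'
#' Describes an idealized arch: two straight arms joined by a circular bend,
#' with optional focal stenoses. Units follow clinical reporting: lengths in
#' cm, angle in degrees. The bend angle is the inscribed angle between the arm
#' tangents (180 = straight; the remodelled cephalic arch is ~125 degrees).
#'
#' @param diameter lumen diameter in cm (> 0); default 0.95, the nominal
#'   remodelled arch diameter in dialysis patients
#' @param bend_angle_deg inscribed angle in degrees, in (0, 180]; default 125
#' @param arm_length_pre,arm_length_post straight arm lengths in cm
#' @param bend_radius centerline radius of the circular bend in cm;
#'   must be at least `diameter / 2`
#' @param stenoses list of focal stenoses, each a list/vector with elements
#'   `arclength_fraction` (strictly inside (0, 1)), `severity` (fractional
#'   area reduction, in \[0, 1)) and `extent` (axial extent in cm)
#' @param seed integer seed used by stochastic renderers consuming this spec
#' @return an object of class `arch_spec`
#' @export
arch_spec <- function(diameter = 0.95, bend_angle_deg = 125,
                      arm_length_pre = 5, arm_length_post = 5,
                      bend_radius = 2, stenoses = list(), seed = 1L) {
  if (!is.numeric(diameter) || diameter <= 0)
    stop("invalid arch spec: 'diameter' must be > 0")
  if (!is.numeric(bend_angle_deg) || bend_angle_deg <= 0 || bend_angle_deg > 180)
    stop("invalid arch spec: 'bend_angle_deg' must be in (0, 180]")
  if (arm_length_pre <= 0 || arm_length_post <= 0)
    stop("invalid arch spec: 'arm_length_pre'/'arm_length_post' must be > 0")
  if (bend_radius < diameter / 2)
    stop("invalid arch spec: 'bend_radius' must be >= diameter/2")
  if (length(stenoses) && !is.null(names(stenoses)) &&
      all(c("arclength_fraction", "severity") %in% names(stenoses)))
    stenoses <- list(stenoses)  # single stenosis passed bare
  stenoses <- lapply(stenoses, function(st) {
    st <- as.list(st)
    if (is.null(st$arclength_fraction) || st$arclength_fraction <= 0 ||
        st$arclength_fraction >= 1)
      stop("invalid arch spec: stenosis 'arclength_fraction' must be in (0, 1)")
    if (is.null(st$severity) || st$severity < 0 || st$severity >= 1)
      stop("invalid arch spec: stenosis 'severity' must be in [0, 1)")
    if (is.null(st$extent) || st$extent <= 0)
      stop("invalid arch spec: stenosis 'extent' must be > 0")
    st[c("arclength_fraction", "severity", "extent")]
  })
  structure(list(diameter = diameter, bend_angle_deg = bend_angle_deg,
                 arm_length_pre = arm_length_pre,
                 arm_length_post = arm_length_post,
                 bend_radius = bend_radius, stenoses = stenoses,
                 seed = as.integer(seed)),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf(paste0("<arch_spec> d = %.2f cm, bend %.0f deg (R = %.2f cm), ",
                     "arms %.1f/%.1f cm, %d stenosis(es)\n"),
              x$diameter, x$bend_angle_deg, x$bend_radius,
              x$arm_length_pre, x$arm_length_post, length(x$stenoses)))
  invisible(x)
}

#' Build the planar centerline of an arch specification
#'
#' Two straight arms joined by a circular arc in the z = 0 plane. The inlet
#' arm runs along +x; the path turns left by the deflection
#' `180 - bend_angle_deg`. Points are spaced at most 0.5 mm apart in
#' arclength, so the total arclength is
#' `arm_pre + arm_post + bend_radius * deflection` (deflection in radians).
#'
#' @param spec an [arch_spec()]
#' @param spacing point spacing in mm (default 0.25, always <= 0.5)
#' @return a [centerline_path()] in mm
#' @export
make_arch_centerline <- function(spec, spacing = 0.25) {
  stopifnot(inherits(spec, "arch_spec"))
  spacing <- min(spacing, 0.5)
  pre <- spec$arm_length_pre * 10     # cm -> mm
  post <- spec$arm_length_post * 10
  Rb <- spec$bend_radius * 10
  defl <- (180 - spec$bend_angle_deg) * pi / 180
  # inlet arm along +x from the origin
  s1 <- seq(0, pre, by = spacing)
  p1 <- cbind(s1, 0)
  if (defl < 1e-12) {
    # straight vessel: one line
    s_all <- seq(0, pre + post, by = spacing)
    return(centerline_path(cbind(s_all, 0)))
  }
  ctr <- c(pre, Rb)                   # bend center (turning left, towards +y)
  arc_len <- Rb * defl
  n_arc <- max(2L, ceiling(arc_len / spacing))
  phi <- seq(0, defl, length.out = n_arc + 1L)[-1L]
  p2 <- cbind(ctr[1L] + Rb * sin(phi), ctr[2L] - Rb * cos(phi))
  # exit direction after the full deflection
  dir2 <- c(cos(defl), sin(defl))
  t2 <- p2[nrow(p2), ]
  s3 <- seq(spacing, post, by = spacing)
  if (s3[length(s3)] < post) s3 <- c(s3, post)
  p3 <- cbind(t2[1L] + dir2[1L] * s3, t2[2L] + dir2[2L] * s3)
  centerline_path(rbind(p1, p2, p3))
}

#' Per-station lumen radius of an arch specification
#'
#' Radius (mm) of the circular cross-section at arclength positions `s_mm`,
#' with each stenosis applied as a cosine-tapered area reduction: over its
#' extent, the cross-sectional area is scaled by `1 - severity * w(s)` where
#' `w` rises smoothly from 0 to 1 at the stenosis center (so the radius scales
#' by the square root). The smooth taper avoids step discontinuities that
#' would create meshing and solver artifacts.
#'
#' @param spec an [arch_spec()]
#' @param s_mm arclength positions in mm
#' @param total_length_mm total arclength in mm used to place
#'   `arclength_fraction`; defaults to the spec's own centerline length
#' @return numeric vector of radii in mm
#' @export
arch_radius_profile <- function(spec, s_mm, total_length_mm = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  if (is.null(total_length_mm)) {
    defl <- (180 - spec$bend_angle_deg) * pi / 180
    total_length_mm <- (spec$arm_length_pre + spec$arm_length_post +
                          spec$bend_radius * defl) * 10
  }
  area_scale <- rep(1, length(s_mm))
  for (st in spec$stenoses) {
    c_mm <- st$arclength_fraction * total_length_mm
    half <- st$extent * 10 / 2
    inside <- abs(s_mm - c_mm) < half
    w <- numeric(length(s_mm))
    w[inside] <- 0.5 * (1 + cos(pi * (s_mm[inside] - c_mm) / half))
    area_scale <- area_scale * (1 - st$severity * w)
  }
  (spec$diameter * 10 / 2) * sqrt(area_scale)
}
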