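#' Wall shear stress field
#'
#' Samples near-wall fluid cells (between half and one-and-a-half cells from
#' the lumen surface, the first fully interior ring, where discrete
#' velocities are accurate) and estimates the wall shear stress as
#' `tau = eta * u_t / d`, the tangential speed at the cell center
#' extrapolated one-sidedly to the wall over the true wall distance `d`,
#' with the quadratic near-wall correction `1 / (1 - d / 2r)` that makes the
#' estimate exact for Poiseuille flow. Equivalent to the product of the
#' local shear rate and the measured whole blood viscosity.
#'
#' @param field a `flow_field`
#' @param eta viscosity Pa s (defaults to the field's fluid properties)
#' @return object of class `wall_field`: `idx` (positions in the fluid-cell
#'   ordering), `tau` (Pa, >= 0), `s_frac` (arclength fraction), `inner`
#'   (logical: inner wall of the bend, `NA` where the vessel is locally
#'   straight), `xyz` (m)
#' @export
compute_wss <- function(field, eta = NULL) {
  dom <- field$domain
  if (is.null(eta)) eta <- field$props$viscosity
  h <- dom$h
  gap <- dom$r_cell - dom$dist_cell          # distance to wall (m)
  # sample only the solved region (prescribed inlet/outlet slabs and the end
  # caps carry boundary artifacts, not physical wall shear)
  wall <- which(gap > 0.5 * h & gap < 1.5 * h &
                  dom$s_cell > dom$inlet_s + h & dom$s_cell < dom$outlet_s - h)
  uc <- cell_velocity(field)[wall, , drop = FALSE]
  nrm <- dom$radial_cell[wall, , drop = FALSE]
  un <- rowSums(uc * nrm)
  ut <- sqrt(pmax(rowSums(uc^2) - un^2, 0))
  d <- gap[wall]
  corr <- 1 / (1 - d / (2 * dom$r_cell[wall]))
  tau <- eta * ut / d * corr
  curv <- station_curvature_dirs(dom)
  cd <- curv$at(dom$s_cell[wall])
  inner <- rowSums(nrm * cd) > 0
  inner[!is.finite(rowSums(cd))] <- NA
  structure(list(idx = wall, tau = tau,
                 s_frac = dom$s_cell[wall] / dom$s_total,
                 inner = inner, xyz = dom$cell_xyz[wall, , drop = FALSE],
                 d_wall = d, eta = eta),
            class = "wall_field")
}

#' @export
print.wall_field <- function(x, ...) {
  cat(sprintf("<wall_field> %d wall samples, WSS %.3g-%.3g Pa (median %.3g)\n",
              length(x$tau), min(x$tau), max(x$tau), stats::median(x$tau)))
  invisible(x)
}

# unit vectors toward the local center of curvature, as a function of
# arclength (NA where the centerline is locally straight)
station_curvature_dirs <- function(dom) {
  g <- dom$geom
  s <- g$station_s * 1e-3
  tg <- g$tangents
  n <- nrow(tg)
  dT <- matrix(0, n, 3L)
  if (n > 2L)
    dT[2:(n - 1L), ] <- tg[3:n, , drop = FALSE] - tg[1:(n - 2L), , drop = FALSE]
  mag <- sqrt(rowSums(dT^2))
  dirs <- dT / ifelse(mag > 1e-3, mag, NA)
  list(at = function(sq) {
    sapply(1:3, function(j) {
      if (sum(is.finite(dirs[, j])) < 2L) return(rep(NA_real_, length(sq)))
      stats::approx(s, dirs[, j], xout = pmin(sq, max(s)), rule = 2L)$y
    })
  })
}

#' Cell Reynolds number field
#'
#' `Re_cell = rho |u| h / eta` per fluid cell, with `h` the local mesh
#' element size; comparable across vessels, patients and flow conditions.
#'
#' @param field a `flow_field`
#' @param props a [fluid_properties()] (defaults to the field's)
#' @return numeric vector over fluid cells (ordered as
#'   `field$domain$cell_index`)
#' @export
compute_re_cell <- function(field, props = NULL) {
  if (is.null(props)) props <- field$props
  uc <- cell_velocity(field)
  props$density * sqrt(rowSums(uc^2)) * field$domain$h / props$viscosity
}

#' Shear rate magnitude field
#'
#' `sqrt(2 D : D)` with `D` the symmetric velocity-gradient tensor, from
#' central differences of cell-centered velocities.
#'
#' @param field a `flow_field`
#' @return numeric vector over fluid cells (1/s)
#' @export
shear_rate_field <- function(field) {
  dom <- field$domain
  h <- dom$h
  dm <- dom$dims
  full <- lapply(1:3, function(d) {
    a <- array(0, dm)
    a[dom$cell_index] <- cell_velocity(field)[, d]
    a
  })
  grad <- function(a, ax)
    (shift_arr(a, ax, -1L) - shift_arr(a, ax, +1L)) / (2 * h)
  G <- vector("list", 9L)
  k <- 1L
  for (i in 1:3) for (j in 1:3) {
    G[[k]] <- grad(full[[i]], j)
    k <- k + 1L
  }
  gd <- function(i, j) G[[(i - 1L) * 3L + j]]
  s2 <- array(0, dm)
  for (i in 1:3) for (j in 1:3) {
    D <- 0.5 * (gd(i, j) + gd(j, i))
    s2 <- s2 + 2 * D * D
  }
  sqrt(s2)[dom$cell_index]
}

#' Maxima of velocity, pressure and WSS per vessel region
#'
#' For each of the pre-bend, bend and post-bend regions, one cross-sectional
#' slice is selected (`slice_rule = "midpoint"`, the region's arclength
#' midpoint, by default; `"random"` draws uniformly within the region under
#' an explicit seed for reproducibility) and the maxima of speed, pressure
#' and wall shear stress on that slice are reported.
#'
#' @param field a `flow_field`
#' @param wall optional `wall_field` from [compute_wss()] (computed if
#'   missing)
#' @param slice_rule `"midpoint"` or `"random"`
#' @param seed seed for `"random"` slices
#' @return data.frame with one row per region (`region`, `s_mm`,
#'   `max_velocity_m_s`, `max_pressure_pa`, `max_wss_pa`); a region with no
#'   cells is flagged with `NA`s
#' @export
region_maxima <- function(field, wall = NULL,
                          slice_rule = c("midpoint", "random"), seed = 1L) {
  slice_rule <- match.arg(slice_rule)
  dom <- field$domain
  geom <- dom$geom
  if (is.null(wall)) wall <- compute_wss(field)
  uc <- cell_velocity(field)
  speed <- sqrt(rowSums(uc^2))
  s_cell_mm <- dom$s_cell * 1e3
  regions <- c("pre-bend", "bend", "post-bend")
  pick <- function(lo, hi) {
    if (slice_rule == "midpoint") (lo + hi) / 2
    else with_seed(seed, stats::runif(1L, lo, hi))
  }
  h_mm <- dom$h * 1e3
  rows <- lapply(regions, function(rg) {
    s_rg <- geom$station_s[geom$region_label == rg]
    if (!length(s_rg))
      return(data.frame(region = rg, s_mm = NA_real_, max_velocity_m_s = NA_real_,
                        max_pressure_pa = NA_real_, max_wss_pa = NA_real_))
    # keep the slice inside the solved (non-prescribed) part of the domain
    lo <- max(min(s_rg), dom$inlet_s * 1e3 + h_mm)
    hi <- min(max(s_rg), dom$outlet_s * 1e3 - h_mm)
    s0 <- pick(lo, hi)
    band <- abs(s_cell_mm - s0) <= h_mm / 2
    if (!any(band)) band <- abs(s_cell_mm - s0) <= h_mm
    wb <- abs(wall$s_frac * dom$s_total * 1e3 - s0) <= 1.5 * h_mm
    data.frame(region = rg, s_mm = s0,
               max_velocity_m_s = max(speed[band]),
               max_pressure_pa = max(field$p[band]),
               max_wss_pa = if (any(wb)) max(wall$tau[wb]) else NA_real_)
  })
  do.call(rbind, rows)
}

# trilinear interpolation of per-fluid-cell values at physical points (m);
# cells outside the fluid contribute zero
interp_cell_values <- function(dom, vals, pts) {
  dm <- dom$dims
  a <- array(0, dm)
  a[dom$cell_index] <- vals
  g <- (pts - matrix(dom$origin, nrow(pts), 3L, byrow = TRUE)) / dom$h + 0.5
  i0 <- pmin(pmax(floor(g), 1), matrix(dm - 1L, nrow(pts), 3L, byrow = TRUE))
  f <- g - i0
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1L] + (1 - dx) * (1 - f[, 1L])) *
      (dy * f[, 2L] + (1 - dy) * (1 - f[, 2L])) *
      (dz * f[, 3L] + (1 - dz) * (1 - f[, 3L]))
    lin <- (i0[, 1L] + dx) + (i0[, 2L] + dy - 1L) * dm[1L] +
      (i0[, 3L] + dz - 1L) * dm[1L] * dm[2L]
    out <- out + w * a[lin]
  }
  out
}

#' Normalized cross-sectional velocity profile
#'
#' Samples the speed along the in-plane diameter lying in the bend plane at
#' one station, normalizes by the profile maximum, and maps the abscissa to
#' \[-1, 1\] with the inner wall (towards the bend's center of curvature)
#' negative and the tube center at zero.
#'
#' @param field a `flow_field`
#' @param station station index into the geometry's stations
#' @param n_samples points across the diameter (default 41)
#' @return data.frame (`xi`, `u_norm`) with attribute `u_max` (m/s)
#' @export
velocity_profile <- function(field, station, n_samples = 41L) {
  dom <- field$domain
  geom <- dom$geom
  stopifnot(station >= 1L, station <= length(geom$station_s))
  s0 <- geom$station_s[station] * 1e-3
  if (s0 <= dom$inlet_s || s0 >= dom$outlet_s)
    stop("station lies in the capped inlet/outlet region")
  ctr <- sapply(1:3, function(j)
    stats::approx(geom$station_s * 1e-3, geom$centers[, j] * 1e-3, xout = s0)$y)
  tg <- sapply(1:3, function(j)
    stats::approx(geom$station_s * 1e-3, geom$tangents[, j], xout = s0)$y)
  tg <- tg / sqrt(sum(tg^2))
  pc <- stats::prcomp(geom$tangents, center = TRUE)
  pn <- pc$rotation[, 3L]                  # bend plane normal
  e <- c(pn[2L] * tg[3L] - pn[3L] * tg[2L],
         pn[3L] * tg[1L] - pn[1L] * tg[3L],
         pn[1L] * tg[2L] - pn[2L] * tg[1L])
  e <- e / sqrt(sum(e^2))
  curv <- station_curvature_dirs(dom)
  # orient +e away from the bend's center of curvature (outer wall positive)
  cd <- curv$at(dom$s_total * seq(0.05, 0.95, length.out = 19L))
  cd <- cd[is.finite(rowSums(cd)), , drop = FALSE]
  if (nrow(cd) && sum(colMeans(cd) * e) > 0) e <- -e
  r0 <- stats::approx(geom$station_s * 1e-3,
                      geom$station_diameter * 1e-2 / 2, xout = s0)$y
  xi <- seq(-1, 1, length.out = n_samples)
  pts <- matrix(ctr, n_samples, 3L, byrow = TRUE) +
    outer(xi * r0 * 0.98, e)
  uc <- cell_velocity(field)
  comps <- sapply(1:3, function(d) interp_cell_values(dom, uc[, d], pts))
  sp <- sqrt(rowSums(comps^2))
  um <- max(sp)
  structure(data.frame(xi = xi, u_norm = sp / um), u_max = um)
}

#' Asymmetry index of a normalized velocity profile
#'
#' `|u_inner - u_outer| / u_max`, with `u_inner` and `u_outer` the peak
#' speeds over the inner and outer half-diameters of the normalized profile.
#' Zero for an axisymmetric profile. A pure lateral tilt of an otherwise
#' parabolic profile — the `O(a / R_bend)` curvature effect that is present
#' in a curved pipe even in creeping flow — moves the peak without changing
#' its height, and so contributes only at second order; the first-order
#' signal is the inertial (Dean) flattening and skewing of the profile at
#' high Reynolds number.
#'
#' @param profile output of [velocity_profile()]
#' @return dimensionless index in \[0, 1\]
#' @export
asymmetry_index <- function(profile) {
  p <- profile$u_norm / max(profile$u_norm)
  inner <- p[profile$xi < 0]
  outer <- p[profile$xi > 0]
  abs(max(inner) - max(outer))
}

#' Detect low-WSS wall patches
#'
#' Flags connected patches of wall samples whose WSS lies below the given
#' percentile of the whole-wall distribution; patches of more than one cell
#' are reported with their arclength fraction and wall side.
#'
#' @param wall a `wall_field` from [compute_wss()]
#' @param dom the `fluid_domain` the wall field was computed on
#' @param percentile WSS percentile defining "low" (default 10)
#' @return ROI data.frame (`kind`, `arclength_fraction`, `extent_mm`,
#'   `score`, `side`), ordered by arclength
#' @export
detect_low_wss <- function(wall, dom, percentile = 10) {
  if (percentile <= 0) return(cbind(empty_roi(), side = character()))
  thr <- stats::quantile(wall$tau, percentile / 100)
  low <- which(wall$tau < thr)
  if (!length(low)) return(cbind(empty_roi(), side = character()))
  cl <- cluster_cells(dom$cell_index[wall$idx[low]], dom$dims)
  med <- stats::median(wall$tau)
  rois <- lapply(split(seq_along(low), cl), function(g) {
    if (length(g) < 2L) return(NULL)
    sf <- wall$s_frac[low[g]]
    side <- wall$inner[low[g]]
    frac_inner <- mean(side, na.rm = TRUE)
    data.frame(kind = "low_wss",
               arclength_fraction = mean(sf),
               extent_mm = max(diff(range(sf)) * dom$s_total * 1e3, dom$h * 1e3),
               score = 1 - mean(wall$tau[low[g]]) / med,
               side = if (!is.finite(frac_inner)) NA_character_
                      else if (frac_inner > 0.5) "inner" else "outer")
  })
  rois <- do.call(rbind, rois)
  if (is.null(rois)) return(cbind(empty_roi(), side = character()))
  rois[order(rois$arclength_fraction), , drop = FALSE]
}

# label connected components (6-connectivity) among a set of cell linear
# indices
cluster_cells <- function(cell_lin, dims) {
  n <- length(cell_lin)
  if (n == 0L) return(integer())
  pos <- arrayInd(cell_lin, dims)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  edges <- NULL
  for (ax in 1:3) {
    nb <- cell_lin + strides[ax]
    j <- match(nb, cell_lin)
    ok <- pos[, ax] < dims[ax] & !is.na(j)
    if (any(ok)) edges <- c(edges, rbind(which(ok), j[ok]))
  }
  if (is.null(edges))
    return(seq_len(n))
  g <- igraph::make_graph(as.vector(edges), n = n, directed = FALSE)
  igraph::components(g)$membership
}

#' Detect flow recirculation (retrograde axial flow)
#'
#' Flags fluid cells whose velocity has a component opposite the local
#' centerline tangent (beyond a small fraction of the inlet velocity),
#' clusters them, and reports recirculation when the largest cluster exceeds
#' `min_cells`.
#'
#' @param field a `flow_field`
#' @param rel_threshold retrograde speed threshold relative to the inlet
#'   mean velocity (default 0.02)
#' @param min_cells cluster size that counts as recirculation (default 5)
#' @return list: `flag`, `n_cells` (largest cluster), `cell_positions`
#' @export
detect_recirculation <- function(field, rel_threshold = 0.02, min_cells = 5L) {
  dom <- field$domain
  uc <- cell_velocity(field)
  axial <- rowSums(uc * dom$tangent_cell)
  uref <- max(abs(field$inlet_mean_velocity), 1e-9)
  # only the solved region (prescribed inlet/outlet slabs excluded)
  free <- dom$ctype[dom$cell_index] == 1L
  rec <- which(axial < -rel_threshold * uref & free)
  if (!length(rec))
    return(list(flag = FALSE, n_cells = 0L, cell_positions = NULL))
  cl <- cluster_cells(dom$cell_index[rec], dom$dims)
  big <- max(tabulate(cl))
  list(flag = big > min_cells, n_cells = big,
       cell_positions = dom$cell_xyz[rec, , drop = FALSE])
}

#' Mean pressure drop between two cross-sections
#'
#' @param field a `flow_field`
#' @param s_frac1,s_frac2 arclength fractions of the two sections
#' @return pressure difference p(s1) - p(s2), Pa
#' @export
pressure_drop <- function(field, s_frac1, s_frac2) {
  dom <- field$domain
  h <- dom$h
  band <- function(fr) {
    s0 <- fr * dom$s_total
    sel <- abs(dom$s_cell - s0) <= h & dom$ctype[dom$cell_index] == 1L
    if (!any(sel)) stop("no free cells at the requested section")
    mean(field$p[sel])
  }
  band(s_frac1) - band(s_frac2)
}
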