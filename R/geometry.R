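#' Vessel geometry: lofted lumen surface with station metrics
#'
#' A `vessel_geometry` bundles the watertight triangulated lumen surface, the
#' centerline it was built on, per-station cross-sectional area (cm^2) and
#' equivalent diameter (cm), per-station region labels
#' (pre-bend / bend / post-bend), and the measured arch angle. Coordinates
#' are millimetres.
#'
#' @name vessel_geometry
NULL

#' Place lumen contours perpendicular to a centerline
#'
#' Each contour is centered on the path point at `k * spacing_mm` arclength
#' and rotated into the plane normal to the local tangent. In-plane frames
#' are propagated by parallel transport along the path (rotating the previous
#' frame by the minimal rotation between consecutive tangents), which avoids
#' the axial twist flips that Frenet frames produce at inflections.
#'
#' @param path a [centerline_path()]
#' @param stack a [lumen_contour_stack()] (or list of [lumen_contour()])
#' @param spacing_mm arclength interval between stations (default 1)
#' @return list of class `ring_set`: `rings` (list of n x 3 vertex matrices),
#'   `s_mm`, `area_cm2`, `centers`, `tangents`
#' @export
place_contours <- function(path, stack, spacing_mm = 1.0) {
  contours <- if (inherits(stack, "lumen_contour_stack")) stack$contours
  else stack
  n <- length(contours)
  if (n < 1L) stop("no contours to place")
  L <- path_length(path)
  n_max <- floor(L / spacing_mm) + 1L
  if (n > n_max)
    stop(sprintf("stack longer than path: %d contours need %.1f mm but path is %.1f mm",
                 n, (n - 1) * spacing_mm, L))
  s_tar <- (seq_len(n) - 1L) * spacing_mm
  centers <- sapply(1:3, function(j)
    stats::approx(path$s, path$points[, j], xout = s_tar)$y)
  if (n == 1L) centers <- matrix(centers, 1L)
  tangents <- sapply(1:3, function(j)
    stats::approx(path$s, path$tangent[, j], xout = s_tar)$y)
  if (n == 1L) tangents <- matrix(tangents, 1L)
  tangents <- tangents / sqrt(rowSums(tangents^2))
  # parallel-transport frames
  e1 <- matrix(0, n, 3L)
  t0 <- tangents[1L, ]
  ref <- if (abs(t0[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * t0) * t0
  e1[1L, ] <- v / sqrt(sum(v^2))
  if (n > 1L) for (k in 2:n) {
    a <- tangents[k - 1L, ]; b <- tangents[k, ]
    cr <- c(a[2L] * b[3L] - a[3L] * b[2L],
            a[3L] * b[1L] - a[1L] * b[3L],
            a[1L] * b[2L] - a[2L] * b[1L])
    s2 <- sum(cr^2)
    if (s2 < 1e-20) {
      e1[k, ] <- e1[k - 1L, ]
    } else {
      # Rodrigues rotation taking a to b, applied to the transported normal
      cs <- sum(a * b)
      x <- e1[k - 1L, ]
      e1[k, ] <- x * cs +
        c(cr[2L] * x[3L] - cr[3L] * x[2L],
          cr[3L] * x[1L] - cr[1L] * x[3L],
          cr[1L] * x[2L] - cr[2L] * x[1L]) +
        cr * sum(cr * x) * (1 - cs) / s2
      e1[k, ] <- e1[k, ] - sum(e1[k, ] * b) * b
      e1[k, ] <- e1[k, ] / sqrt(sum(e1[k, ]^2))
    }
  }
  rings <- vector("list", n)
  areas <- numeric(n)
  for (k in seq_len(n)) {
    ct <- contours[[k]]
    v2 <- sweep(ct$vertices, 2L, ct$centroid_mm)     # center on centroid
    t_ <- tangents[k, ]
    b2 <- c(t_[2L] * e1[k, 3L] - t_[3L] * e1[k, 2L],
            t_[3L] * e1[k, 1L] - t_[1L] * e1[k, 3L],
            t_[1L] * e1[k, 2L] - t_[2L] * e1[k, 1L])
    rings[[k]] <- sweep(outer(v2[, 1L], e1[k, ]) + outer(v2[, 2L], b2),
                        2L, centers[k, ], `+`)
    areas[k] <- ct$area_cm2
  }
  structure(list(rings = rings, s_mm = s_tar, area_cm2 = areas,
                 centers = centers, tangents = tangents),
            class = "ring_set")
}

# resample a closed 3D ring polygon to m points at uniform arclength
resample_ring <- function(v, m) {
  vc <- rbind(v, v[1L, ])
  seg <- sqrt(rowSums(diff(vc)^2))
  s <- c(0, cumsum(seg))
  st <- seq(0, s[length(s)], length.out = m + 1L)[seq_len(m)]
  sapply(1:3, function(j) stats::approx(s, vc[, j], xout = st)$y)
}

#' Loft a ring set into a watertight triangulated surface
#'
#' Rings are resampled to `vertices_per_ring` points, rotationally registered
#' to the previous ring by the cyclic offset minimizing total vertex distance
#' (minimal twist), triangulated between consecutive rings, capped at both
#' ends, and Laplacian-smoothed with a volume-preserving rescale (unbounded
#' smoothing shrinks the lumen, so iterations are limited and volume is
#' restored).
#'
#' @param rings a `ring_set` from [place_contours()], or a plain list of
#'   n x 3 ring vertex matrices
#' @param vertices_per_ring points per ring after resampling (default 64)
#' @param smooth_iters Laplacian smoothing iterations (default 10)
#' @return object of class `vessel_geometry`
#' @export
loft_surface <- function(rings, vertices_per_ring = 64L, smooth_iters = 10L) {
  rs <- if (inherits(rings, "ring_set")) rings
  else list(rings = rings, s_mm = (seq_along(rings) - 1),
            area_cm2 = vapply(rings, ring_area_cm2, numeric(1L)),
            centers = t(vapply(rings, colMeans, numeric(3L))),
            tangents = NULL)
  nr <- length(rs$rings)
  if (nr < 2L) stop("need at least 2 rings to loft")
  m <- as.integer(vertices_per_ring)
  R <- lapply(rs$rings, resample_ring, m = m)
  # minimal-twist cyclic registration to the previous ring
  for (k in 2:nr) {
    prev <- R[[k - 1L]]; cur <- R[[k]]
    best <- 0L; bestd <- Inf
    for (off in 0:(m - 1L)) {
      idx <- ((seq_len(m) - 1L + off) %% m) + 1L
      d <- sum((cur[idx, ] - prev)^2)
      if (d < bestd) { bestd <- d; best <- off }
    }
    idx <- ((seq_len(m) - 1L + best) %% m) + 1L
    R[[k]] <- cur[idx, , drop = FALSE]
  }
  # consecutive rings must not interpenetrate: every vertex of ring k+1 must
  # lie on the forward side of ring k's plane
  for (k in seq_len(nr - 1L)) {
    ck <- colMeans(R[[k]])
    nk <- colMeans(R[[k + 1L]]) - ck
    nk <- nk / sqrt(sum(nk^2))
    if (min(sweep(R[[k + 1L]], 2L, ck) %*% nk) < -1e-9)
      stop("self-intersecting loft (ring spacing smaller than local radius change); use finer ring spacing")
  }
  verts <- do.call(rbind, R)
  vid <- function(k, i) (k - 1L) * m + ((i - 1L) %% m) + 1L
  faces <- vector("list", nr - 1L)
  for (k in seq_len(nr - 1L)) {
    i <- seq_len(m)
    faces[[k]] <- rbind(cbind(vid(k, i), vid(k, i + 1L), vid(k + 1L, i)),
                        cbind(vid(k + 1L, i), vid(k, i + 1L), vid(k + 1L, i + 1L)))
  }
  faces <- do.call(rbind, faces)
  # end caps: triangle fans about the ring centroids
  c1 <- nrow(verts) + 1L; c2 <- nrow(verts) + 2L
  verts <- rbind(verts, colMeans(R[[1L]]), colMeans(R[[nr]]))
  i <- seq_len(m)
  faces <- rbind(faces,
                 cbind(rep(c1, m), vid(1L, i + 1L), vid(1L, i)),
                 cbind(rep(c2, m), vid(nr, i), vid(nr, i + 1L)))
  if (smooth_iters > 0L) {
    adj <- face_adjacency(faces, nrow(verts))
    v0 <- mesh_volume(verts, faces)
    ctr0 <- colMeans(verts)
    deg <- Matrix::rowSums(adj)
    for (it in seq_len(smooth_iters)) {
      nbavg <- as.matrix(adj %*% verts) / deg
      verts <- 0.5 * verts + 0.5 * nbavg
    }
    v1 <- mesh_volume(verts, faces)
    verts <- sweep(sweep(verts, 2L, colMeans(verts)) * (v0 / v1)^(1 / 3),
                   2L, ctr0, `+`)
  }
  area <- rs$area_cm2
  structure(list(vertices = verts, faces = faces,
                 rings = R, n_rings = nr, vertices_per_ring = m,
                 station_s = rs$s_mm, station_area = area,
                 station_diameter = diameter_from_area(area),
                 region_label = rep("pre-bend", nr),
                 centers = rs$centers, tangents = rs$tangents,
                 centerline = if (nr > 2L) centerline_path(rs$centers) else NULL,
                 arch_angle_deg = NA_real_),
            class = "vessel_geometry")
}

ring_area_cm2 <- function(ring) {
  # area of a planar 3D ring via its best-fit plane
  ctr <- colMeans(ring)
  v <- sweep(ring, 2L, ctr)
  pc <- stats::prcomp(v, center = FALSE)
  polygon_area(v %*% pc$rotation[, 1:2], check = FALSE)
}

# sparse vertex adjacency from a face matrix
face_adjacency <- function(faces, nv) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3L, 1L)])
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(nv, nv), use.last.ij = TRUE)
}

#' Watertightness check
#'
#' A closed surface has every undirected edge shared by exactly two faces.
#'
#' @param geom a `vessel_geometry` (or list with `vertices`/`faces`)
#' @return `TRUE` if watertight
#' @export
is_watertight <- function(geom) {
  f <- geom$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' Enclosed volume of a closed triangulated surface (mm^3)
#' @param verts vertex matrix; @param faces face index matrix
#' @export
mesh_volume <- function(verts, faces) {
  a <- verts[faces[, 1L], , drop = FALSE]
  b <- verts[faces[, 2L], , drop = FALSE]
  c_ <- verts[faces[, 3L], , drop = FALSE]
  abs(sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) +
            a[, 2L] * (b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]) +
            a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6)
}

#' Total surface area of a triangulated mesh (mm^2)
#' @param verts vertex matrix; @param faces face index matrix
#' @export
mesh_area <- function(verts, faces) {
  a <- verts[faces[, 1L], , drop = FALSE]
  u <- verts[faces[, 2L], , drop = FALSE] - a
  v <- verts[faces[, 3L], , drop = FALSE] - a
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(paste0("<vessel_geometry> %d rings x %d vertices, %d faces; ",
                     "length %.1f mm, mean diameter %.2f cm%s\n"),
              x$n_rings, x$vertices_per_ring, nrow(x$faces),
              max(x$station_s), mean(x$station_diameter),
              if (is.na(x$arch_angle_deg)) ""
              else sprintf(", arch angle %.0f deg", x$arch_angle_deg)))
  invisible(x)
}

#' Demarcate pre-bend, bend and post-bend regions
#'
#' The signed in-plane turning angle of the centerline is accumulated along
#' arclength (signed so that pixel-level tangent noise cancels); the bend is
#' the smallest contiguous station window containing `turning_fraction` of
#' the total turning, the upstream remainder is pre-bend and the downstream
#' remainder post-bend.
#'
#' @param geom a `vessel_geometry`
#' @param turning_fraction fraction of total turning the bend window must
#'   contain (default 0.8)
#' @return the geometry with `region_label` filled in; a straight vessel is
#'   labelled all pre-bend with a warning
#' @export
demarcate_regions <- function(geom, turning_fraction = 0.8) {
  stopifnot(inherits(geom, "vessel_geometry"),
            turning_fraction > 0, turning_fraction <= 1)
  tang <- geom$tangents
  if (is.null(tang)) stop("geometry carries no station tangents")
  n <- nrow(tang)
  # best-fit bend plane from the tangent directions
  pc <- stats::prcomp(tang, center = TRUE)
  u <- pc$rotation[, 1L]; v <- pc$rotation[, 2L]
  theta <- unwrap_angle(atan2(tang %*% v, tang %*% u))
  total <- theta[n] - theta[1L]
  if (abs(total) < 1e-3) {
    warning("no bend detected; all stations labelled pre-bend")
    geom$region_label <- rep("pre-bend", geom$n_rings)
    return(geom)
  }
  target <- turning_fraction * abs(total)
  best <- c(1L, n)
  for (i in seq_len(n)) {
    j <- which(abs(theta - theta[i]) >= target & seq_len(n) > i)
    if (length(j)) {
      j <- j[1L]
      if (j - i < best[2L] - best[1L]) best <- c(i, j)
    }
  }
  lab <- rep("pre-bend", n)
  lab[best[1L]:best[2L]] <- "bend"
  if (best[2L] < n) lab[(best[2L] + 1L):n] <- "post-bend"
  geom$region_label <- lab
  geom
}

unwrap_angle <- function(th) {
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(th[1L], th[1L] + cumsum(d))
}

#' Build an idealized arch geometry
#'
#' A cylindrical tube of the given diameter bent at the given angle — the
#' idealized remodelled cephalic arch (0.95 cm diameter, 125 degrees by
#' default). Cross-sections are circles placed at 1 mm stations along the
#' parametric centerline, lofted, and demarcated into
#' pre-bend / bend / post-bend.
#'
#' @param diameter lumen diameter, cm
#' @param bend_angle inscribed bend angle, degrees
#' @param arm_length_pre,arm_length_post,bend_radius,stenoses,seed passed to
#'   [arch_spec()]
#' @param spacing_mm station spacing (default 1)
#' @param vertices_per_ring,smooth_iters passed to [loft_surface()]
#' @return a `vessel_geometry`
#' @export
make_idealized_arch <- function(diameter = 0.95, bend_angle = 125,
                                arm_length_pre = 3, arm_length_post = 3,
                                bend_radius = 2, stenoses = list(), seed = 1L,
                                spacing_mm = 1.0, vertices_per_ring = 64L,
                                smooth_iters = 0L) {
  spec <- arch_spec(diameter, bend_angle, arm_length_pre, arm_length_post,
                    bend_radius, stenoses, seed)
  path <- make_arch_centerline(spec)
  L <- path_length(path)
  s_st <- seq(0, L, by = spacing_mm)
  radii <- arch_radius_profile(spec, s_st, L)
  ang <- seq(0, 2 * pi, length.out = 65L)[-65L]
  contours <- lapply(seq_along(s_st), function(k)
    lumen_contour(k, cbind(radii[k] * cos(ang), radii[k] * sin(ang))))
  rings <- place_contours(path, contours, spacing_mm)
  geom <- loft_surface(rings, vertices_per_ring, smooth_iters)
  geom$arch_angle_deg <- measure_arch_angle(path)
  geom$spec <- spec
  demarcate_regions(geom)
}

#' Detect constriction regions of interest
#'
#' Flags local minima of the per-station area profile whose area falls below
#' `rel_threshold` times the median area over the surrounding neighbourhood.
#' The score is `1 - min_area / neighbourhood_median` (a 40 percent stenosis
#' scores about 0.4).
#'
#' @param geom a `vessel_geometry`
#' @param rel_threshold relative area triggering a constriction (default 0.8)
#' @param neighborhood_mm arclength neighbourhood for the reference median
#'   (default 10)
#' @return data.frame of ROIs (`kind`, `arclength_fraction`, `extent_mm`,
#'   `score`), ordered by arclength; empty if none
#' @export
detect_constrictions <- function(geom, rel_threshold = 0.8,
                                 neighborhood_mm = 10) {
  a <- geom$station_area
  s <- geom$station_s
  n <- length(a)
  if (n < 3L) stop("need at least 3 stations")
  rois <- empty_roi()
  i <- 2L
  while (i < n) {
    if (a[i] <= a[i - 1L] && a[i] <= a[i + 1L]) {
      nb <- abs(s - s[i]) <= neighborhood_mm & abs(s - s[i]) > 1e-9
      ref <- stats::median(a[nb])
      if (a[i] < rel_threshold * ref) {
        below <- a < rel_threshold * ref
        lo <- i; while (lo > 1L && below[lo - 1L]) lo <- lo - 1L
        hi <- i; while (hi < n && below[hi + 1L]) hi <- hi + 1L
        rois <- rbind(rois, data.frame(
          kind = "constriction",
          arclength_fraction = s[i] / max(s),
          extent_mm = s[hi] - s[lo] + mean(diff(s)),
          score = 1 - a[i] / ref))
        i <- hi + 1L
        next
      }
    }
    i <- i + 1L
  }
  rois[order(rois$arclength_fraction), , drop = FALSE]
}

empty_roi <- function() {
  data.frame(kind = character(), arclength_fraction = numeric(),
             extent_mm = numeric(), score = numeric())
}

#' Match regions of interest between two timepoints
#'
#' Greedy nearest-neighbour pairing on arclength fraction: the closest pair
#' within `tol_fraction` is matched first, then the next, until none remain.
#'
#' @param rois_t1,rois_t2 ROI data.frames from the same vessel at two
#'   timepoints
#' @param tol_fraction maximum arclength-fraction separation (default 0.05)
#' @return list with `pairs` (data.frame `index_t1`, `index_t2`,
#'   `separation`) and `unmatched_t1` / `unmatched_t2` index vectors
#' @export
match_rois <- function(rois_t1, rois_t2, tol_fraction = 0.05) {
  n1 <- nrow(rois_t1); n2 <- nrow(rois_t2)
  pairs <- data.frame(index_t1 = integer(), index_t2 = integer(),
                      separation = numeric())
  if (n1 && n2) {
    d <- abs(outer(rois_t1$arclength_fraction, rois_t2$arclength_fraction, `-`))
    repeat {
      k <- which.min(d)
      if (!length(k) || d[k] > tol_fraction) break
      i <- (k - 1L) %% n1 + 1L; j <- (k - 1L) %/% n1 + 1L
      pairs <- rbind(pairs, data.frame(index_t1 = i, index_t2 = j,
                                       separation = d[k]))
      d[i, ] <- Inf; d[, j] <- Inf
    }
  }
  list(pairs = pairs,
       unmatched_t1 = setdiff(seq_len(n1), pairs$index_t1),
       unmatched_t2 = setdiff(seq_len(n2), pairs$index_t2))
}
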