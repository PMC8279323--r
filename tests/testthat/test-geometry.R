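circle_contours <- function(n, r_mm, frame_from = 1L) {
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  lapply(seq_len(n), function(i)
    lumen_contour(frame_from + i - 1L, cbind(r_mm * cos(ang), r_mm * sin(ang))))
}

test_that("contours on a straight path form a right cylinder", {
  path <- centerline_path(cbind(seq(0, 30, 0.5), 0))
  rings <- place_contours(path, circle_contours(31, 4), spacing_mm = 1)
  normals <- t(sapply(rings$rings, function(rg) {
    pc <- stats::prcomp(rg)
    pc$rotation[, 3]
  }))
  # all ring normals parallel to the x axis
  expect_true(all(abs(abs(normals[, 1]) - 1) < 1e-9))
  expect_error(place_contours(path, list()), "no contours")
  expect_error(place_contours(path, circle_contours(100, 4)), "longer than path")
})

test_that("ring normals follow tangents within a degree on a bent path", {
  sp <- arch_spec(0.8, 125, 3, 3, 2)
  path <- make_arch_centerline(sp)
  n <- floor(path_length(path)) + 1L
  rings <- place_contours(path, circle_contours(n, 4), spacing_mm = 1)
  for (k in seq(2, n, by = 7)) {
    pc <- stats::prcomp(rings$rings[[k]])
    nrm <- pc$rotation[, 3]
    ct <- abs(sum(nrm * rings$tangents[k, ]))
    expect_gt(ct, cos(1 * pi / 180))
  }
})

circle_contours_rings <- function(n, r_mm) {
  path <- centerline_path(cbind(seq(0, n - 1), 0))
  place_contours(path, circle_contours(n, r_mm), spacing_mm = 1)
}

test_that("lofted cylinder reproduces analytic area and volume", {
  path <- centerline_path(cbind(seq(0, 40, 0.5), 0))
  rings <- place_contours(path, circle_contours(41, 4), spacing_mm = 1)
  geom <- loft_surface(rings, smooth_iters = 0L)
  expect_true(is_watertight(geom))
  wall <- mesh_area(geom$vertices, geom$faces) - 2 * pi * 4^2
  expect_equal(wall, 2 * pi * 4 * 40, tolerance = 0.02)
  vol <- mesh_volume(geom$vertices, geom$faces)
  # prismatoid oracle: trapezoidal sum of area x spacing between stations
  a_mm2 <- geom$station_area * 100
  expect_equal(vol, sum((a_mm2[-1] + a_mm2[-length(a_mm2)]) / 2) * 1,
               tolerance = 0.02)
  # two identical rings still close into a watertight capsule
  g2 <- loft_surface(circle_contours_rings(2, 4), smooth_iters = 0L)
  expect_true(is_watertight(g2))
})

test_that("station diameters of a stenosed arch match the generating spec", {
  st <- list(list(arclength_fraction = 0.5, severity = 0.4, extent = 1.5))
  geom <- make_idealized_arch(stenoses = st)
  sp <- arch_spec(stenoses = st, arm_length_pre = 3, arm_length_post = 3)
  truth_r <- arch_radius_profile(sp, geom$station_s, max(geom$station_s))
  expect_equal(geom$station_diameter, 2 * truth_r / 10, tolerance = 0.03)
})

test_that("region labels partition stations around the bend", {
  geom <- make_idealized_arch()
  expect_equal(sort(unique(geom$region_label)),
               c("bend", "post-bend", "pre-bend"))
  expect_equal(length(geom$region_label), geom$n_rings)
  r <- rle(geom$region_label)$values
  expect_equal(r, c("pre-bend", "bend", "post-bend"))
  # bend window center sits near the arc midpoint (2 cm bend radius)
  s_b <- geom$station_s[geom$region_label == "bend"]
  defl <- (180 - 125) * pi / 180
  arc_mid <- 30 + 20 * defl / 2
  expect_lt(abs(mean(range(s_b)) - arc_mid), 2)
  # full turning fraction covers at least the whole curved arc
  g1 <- demarcate_regions(geom, turning_fraction = 1.0)
  expect_gte(sum(g1$region_label == "bend") + 1L, 20 * defl)
  # straight tube: all pre-bend with a warning
  expect_warning(make_idealized_arch(bend_angle = 180, arm_length_pre = 2,
                                     arm_length_post = 2), "no bend")
})

test_that("idealized arch defaults match the nominal remodelled vessel", {
  geom <- make_idealized_arch()
  expect_true(all(abs(geom$station_diameter - 0.95) < 0.02))
  expect_equal(geom$arch_angle_deg, 125, tolerance = 0.5 / 125)
  expect_true(is_watertight(geom))
})

test_that("constriction detection locates stenoses by arclength", {
  geom <- make_idealized_arch()
  expect_equal(nrow(detect_constrictions(geom)), 0L)
  st <- list(list(arclength_fraction = 0.5, severity = 0.4, extent = 1.5))
  g1 <- make_idealized_arch(stenoses = st)
  r1 <- detect_constrictions(g1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$arclength_fraction, 0.5, tolerance = 0.02 / 0.5)
  expect_gt(r1$score, 0.3)
  two <- list(list(arclength_fraction = 0.3, severity = 0.5, extent = 1),
              list(arclength_fraction = 0.7, severity = 0.3, extent = 1))
  r2 <- detect_constrictions(make_idealized_arch(stenoses = two))
  expect_equal(nrow(r2), 2L)
  expect_true(all(diff(r2$arclength_fraction) > 0))
  expect_equal(r2$arclength_fraction, c(0.3, 0.7), tolerance = 0.05)
})

test_that("ROI matching pairs nearest arclength fractions greedily", {
  r1 <- data.frame(kind = "constriction", arclength_fraction = 0.50,
                   extent_mm = 5, score = 0.4)
  r2 <- data.frame(kind = rep("constriction", 2),
                   arclength_fraction = c(0.53, 0.90),
                   extent_mm = 5, score = 0.3)
  m <- match_rois(r1, r2)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$index_t2, 1L)
  expect_equal(m$unmatched_t2, 2L)
  ident <- match_rois(r2, r2)
  expect_equal(nrow(ident$pairs), 2L)
  expect_equal(ident$pairs$separation, c(0, 0))
  none <- match_rois(r1[0, ], r2)
  expect_equal(nrow(none$pairs), 0L)
})

test_that("reconstruction is rigid-motion equivariant", {
  sp <- arch_spec(0.8, 130, 2, 2, 1.5)
  path <- make_arch_centerline(sp)
  n <- floor(path_length(path)) + 1L
  geom <- loft_surface(place_contours(path, circle_contours(n, 4)),
                       smooth_iters = 0L)
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pr <- centerline_path(path$points %*% R + matrix(c(5, -3, 0), nrow(path$points),
                                                  3, byrow = TRUE))
  gr <- loft_surface(place_contours(pr, circle_contours(n, 4)),
                     smooth_iters = 0L)
  expect_equal(gr$station_area, geom$station_area, tolerance = 0.005)
  expect_equal(mesh_volume(gr$vertices, gr$faces),
               mesh_volume(geom$vertices, geom$faces), tolerance = 0.005)
  expect_equal(measure_arch_angle(centerline_path(gr$centers)),
               measure_arch_angle(centerline_path(geom$centers)),
               tolerance = 0.005)
})

test_that("mesh and station tables export to readable files", {
  geom <- make_idealized_arch(arm_length_pre = 1.5, arm_length_post = 1.5)
  stl <- tempfile(fileext = ".stl"); vtk <- tempfile(fileext = ".vtk")
  csv <- tempfile(fileext = ".csv")
  write_stl(geom, stl)
  write_vtk_surface(geom, vtk)
  write_station_csv(geom, csv)
  expect_gt(file.size(stl), 1000)
  expect_equal(readLines(vtk, n = 1), "# vtk DataFile Version 3.0")
  tab <- read.csv(csv)
  expect_equal(nrow(tab), geom$n_rings)
  unlink(c(stl, vtk, csv))
})
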