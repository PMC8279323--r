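test_that("shoelace area is exact, orientation-free, and guards crossings", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))    # 1 cm side, in mm
  expect_equal(polygon_area(sq), 1.0)
  expect_equal(polygon_area(sq[4:1, ]), 1.0)
  # regular 64-gon, circumradius 1 cm: (1/2) n r^2 sin(2 pi / n)
  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  poly <- cbind(10 * cos(ang), 10 * sin(ang))
  expect_equal(polygon_area(poly), 0.5 * 64 * 1^2 * sin(2 * pi / 64),
               tolerance = 1e-10)
  expect_equal(polygon_area(poly), 3.1365, tolerance = 1e-4)
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(polygon_area(bow), "self-intersecting")
})

test_that("contour extraction recovers a digitized disk within one percent", {
  px <- 0.032                       # 16 mm / 500 px convention
  n <- 256L
  m <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in seq_len(n)) m[i, ] <- ((i - ctr)^2 + (seq_len(n) - ctr)^2 <= 100^2)
  ct <- extract_contour(m, pixel_spacing = px)
  expect_equal(ct$area_cm2, pi * (100 * px / 10)^2, tolerance = 0.01)
  # a 10 x 10 px square
  sqm <- matrix(0L, 32, 32); sqm[10:19, 10:19] <- 1L
  cts <- extract_contour(sqm, pixel_spacing = px)
  expect_equal(cts$area_cm2, (10 * px / 10)^2, tolerance = 0.08)
  # degenerate single-pixel component
  one <- matrix(0L, 16, 16); one[8, 8] <- 1L
  expect_error(extract_contour(one, px), "degenerate")
  # multiple components: largest kept with a warning
  two <- m; two[4:6, 4:6] <- 1L
  expect_warning(ct2 <- extract_contour(two, px), "largest")
  expect_equal(ct2$area_cm2, ct$area_cm2, tolerance = 1e-6)
})

test_that("diameter round-trips through a polygonized circle", {
  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  for (d_cm in c(0.66, 0.95, 1.1)) {
    poly <- cbind(d_cm * 5 * cos(ang), d_cm * 5 * sin(ang))
    expect_equal(diameter_from_area(polygon_area(poly)), d_cm,
                 tolerance = 0.01)
  }
})

test_that("pullback subsampling keeps every n-th frame at 1 mm spacing", {
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  mk <- function(i) lumen_contour(i, cbind(4 * cos(ang) + 8, 4 * sin(ang) + 8))
  frames <- lapply(seq_len(3000), mk)
  st <- subsample_to_spacing(frames, frames_per_mm = 30L)
  expect_equal(length(st$contours), 100L)
  expect_equal(st$slice_spacing, 1.0)
  expect_equal(length(subsample_to_spacing(frames[1:30], 30L)$contours), 1L)
  expect_error(subsample_to_spacing(frames[1:10], 30L), "fewer frames")
})

test_that("lumen summary follows the mean-area convention", {
  ang <- seq(0, 2 * pi, length.out = 129)[-129]
  circle <- function(a_cm2) {
    r_mm <- sqrt(a_cm2 * 100 / pi)
    lumen_contour(1L, cbind(r_mm * cos(ang) + 8, r_mm * sin(ang) + 8))
  }
  # constant-area stack: P93 3-month area maps to the printed diameter
  cs <- lapply(1:5, function(i) { ct <- circle(0.513); ct$frame_index <- i; ct })
  sm <- summarize_lumen(lumen_contour_stack(cs))
  expect_equal(sm$mean_area_cm2, 0.513, tolerance = 2e-3)
  expect_equal(sm$sd_area_cm2, 0, tolerance = 1e-6)
  expect_equal(round(sm$mean_diameter_cm, 2), 0.81)
  # two-slice stack: sample SD, and diameter from the mean area
  ab <- list(circle(0.4), circle(0.6)); ab[[2]]$frame_index <- 2L
  sm2 <- summarize_lumen(lumen_contour_stack(ab))
  expect_equal(sm2$mean_area_cm2, 0.5, tolerance = 2e-3)
  expect_equal(sm2$sd_area_cm2, stats::sd(c(ab[[1]]$area_cm2, ab[[2]]$area_cm2)))
  expect_equal(sm2$mean_diameter_cm, diameter_from_area(sm2$mean_area_cm2))
})

test_that("arch start is found at the axillary diameter shift", {
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  mk <- function(i, r) lumen_contour(i, cbind(r * cos(ang) + 8, r * sin(ang) + 8))
  # 10 slices of 1.5x lead-in then 30 slices of arch
  rs <- c(rep(1.5 * 4.75, 10), rep(4.75, 30))
  st <- lumen_contour_stack(lapply(seq_along(rs), function(i) mk(i, rs[i])))
  idx <- find_arch_start(st)
  expect_true(abs(idx - 11L) <= 2L)
  # constant stack: warning, index 1
  cst <- lumen_contour_stack(lapply(1:20, function(i) mk(i, 4)))
  expect_warning(i0 <- find_arch_start(cst), "no diameter shift")
  expect_equal(as.integer(i0), 1L)
  expect_false(attr(i0, "found"))
  # degenerate threshold trips immediately
  st_noisy <- lumen_contour_stack(lapply(seq_along(rs), function(i)
    mk(i, rs[i] * (1 + 0.001 * (i %% 2)))))
  expect_lte(as.integer(find_arch_start(st_noisy, rel_drop = 0)), 7L)
})

test_that("synthetic pullback summarizes to its specified diameter", {
  rt <- roundtrip_run()
  sub <- subsample_to_spacing(rt$ivus$contours, 30L)
  start <- find_arch_start(sub)
  arch <- lumen_contour_stack(sub$contours[start:length(sub$contours)])
  sm <- summarize_lumen(arch)
  # mean diameter reflects the 0.95 cm arch with its 40% stenosis included
  expect_equal(sm$mean_diameter_cm, 0.95, tolerance = 0.05)
})

test_that("contour IO round-trips through CSV", {
  rt <- roundtrip_run()
  sub <- subsample_to_spacing(rt$ivus$contours, 30L)
  f <- tempfile(fileext = ".csv")
  write_contours_csv(sub, f)
  back <- read_contours_csv(f, slice_spacing = sub$slice_spacing)
  expect_equal(stack_areas(back), stack_areas(sub), tolerance = 1e-8)
  unlink(f)
})
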