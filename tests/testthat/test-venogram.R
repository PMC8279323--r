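test_that("minimum-intensity projection is a pixelwise minimum", {
  f1 <- matrix(runif(12), 3, 4)
  f2 <- matrix(runif(12), 3, 4)
  st <- image_stack(list(f1, f2), pixel_spacing = 0.2)
  expect_equal(min_intensity_projection(st), pmin(f1, f2))
  # single frame is the identity; an all-zeros frame wins everywhere
  expect_equal(min_intensity_projection(image_stack(list(f1), 0.2)), f1)
  z <- matrix(0, 3, 4)
  expect_equal(min_intensity_projection(image_stack(list(f1, z), 0.2)), z)
})

test_that("projection darkens vessel pixels below any single noisy frame", {
  rt <- roundtrip_run()
  proj <- min_intensity_projection(rt$veno)
  # brute-force oracle over the frame list
  ref <- Reduce(pmin, rt$veno$frames)
  expect_equal(proj, ref)
  expect_true(all(proj <= rt$veno$frames[[1]]))
})

test_that("binarization cleans specks and rejects featureless images", {
  img <- matrix(1, 60, 60)
  img[20:40, 10:50] <- 0.1          # vessel block
  img[5, 5] <- 0.05                 # speck below the component threshold
  mask <- binarize_and_clean(img, 0.5, min_component_px = 10L)
  expect_false(mask[5, 5])
  expect_true(all(mask[20:40, 10:50]))
  expect_error(binarize_and_clean(matrix(0.5, 10, 10), 0.5), "no vessel")
})

test_that("skeletonization thins a bar to a single line", {
  m <- matrix(FALSE, 20, 9)
  m[3:18, 4:6] <- TRUE              # 3-pixel-wide horizontal bar
  sk <- skeletonize_mask(m)
  expect_true(all(rowSums(sk[3:18, , drop = FALSE]) <= 1))
  expect_gte(sum(sk), 12)
  # a disk collapses to a few central pixels
  d <- matrix(FALSE, 31, 31)
  ctr <- 16
  for (i in 1:31) for (j in 1:31)
    d[i, j] <- (i - ctr)^2 + (j - ctr)^2 <= 100
  skd <- skeletonize_mask(d)
  expect_lte(sum(skd), 10)
  expect_error(skeletonize_mask(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 10, 10); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(skeletonize_mask(two), "components")
})

test_that("centerline extraction prunes spurs and orders the path", {
  sk <- matrix(FALSE, 40, 20)
  sk[5:35, 10] <- TRUE              # main straight path
  sk[20, 11:14] <- TRUE             # short side spur
  path <- extract_centerline(sk, pixel_spacing = 0.5, smooth_mm = 0)
  expect_lt(max(abs(path$curvature)), 0.01)
  # all path points lie on the main line, none on the spur
  expect_true(all(abs(path$points[, 2] - 0.5 * (10 - 0.5)) < 0.3))
  expect_error(extract_centerline(matrix(FALSE, 5, 5), 0.5), "empty")
  # a pure ring has no endpoints to anchor a path
  ring <- matrix(FALSE, 15, 15)
  for (i in 1:15) for (j in 1:15) {
    r2 <- (i - 8)^2 + (j - 8)^2
    ring[i, j] <- r2 >= 20 & r2 <= 30
  }
  expect_error(extract_centerline(ring, 0.5), "cyclic")
})

test_that("arch angle is recovered from rendered venograms", {
  for (ang in c(125, 150)) {
    sp <- arch_spec(diameter = 0.8, bend_angle_deg = ang,
                    arm_length_pre = 4, arm_length_post = 4, bend_radius = 2)
    cl <- make_arch_centerline(sp)
    vg <- render_venogram(cl, 0.8, pixel_spacing = 0.25, noise_sd = 0.04,
                          seed = 5L, n_frames = 3L)
    path <- process_venogram(vg)
    expect_equal(measure_arch_angle(path), ang, tolerance = 2 / ang)
  }
})

test_that("arch angle is invariant under rigid rotation of the image", {
  sp <- arch_spec(diameter = 0.8, bend_angle_deg = 135, arm_length_pre = 3,
                  arm_length_post = 3, bend_radius = 1.5)
  cl <- make_arch_centerline(sp)
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cl_rot <- centerline_path(cl$points[, 1:2] %*% R)
  a1 <- measure_arch_angle(process_venogram(
    render_venogram(cl, 0.8, 0.25, noise_sd = 0, seed = 1L, n_frames = 1L)))
  a2 <- measure_arch_angle(process_venogram(
    render_venogram(cl_rot, 0.8, 0.25, noise_sd = 0, seed = 1L, n_frames = 1L)))
  expect_equal(a1, a2, tolerance = 1 / 135)
})

test_that("straight-path angle and parallel-arm flag behave", {
  line <- centerline_path(cbind(seq(0, 50, 0.5), 0))
  expect_equal(measure_arch_angle(line), 180)
})
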