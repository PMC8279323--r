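test_that("arch spec validation names the offending field", {
  expect_error(arch_spec(diameter = -1), "diameter")
  expect_error(arch_spec(bend_angle_deg = 200), "bend_angle_deg")
  expect_error(arch_spec(bend_radius = 0.1, diameter = 0.95), "bend_radius")
  expect_error(arch_spec(stenoses = list(list(arclength_fraction = 0,
                                              severity = 0.4, extent = 1))),
               "arclength_fraction")
  expect_error(arch_spec(stenoses = list(list(arclength_fraction = 0.5,
                                              severity = 1, extent = 1))),
               "severity")
})

test_that("arch centerline has the specified bend angle and arclength", {
  sp <- arch_spec(diameter = 0.95, bend_angle_deg = 125,
                  arm_length_pre = 5, arm_length_post = 5, bend_radius = 2)
  cl <- make_arch_centerline(sp)
  expect_equal(measure_arch_angle(cl), 125, tolerance = 0.5 / 125)
  L_expect <- (5 + 5 + 2 * (180 - 125) * pi / 180) * 10     # mm
  expect_equal(path_length(cl), L_expect, tolerance = 1e-3)
  expect_lte(max(diff(cl$s)), 0.5)
  # degenerate bend: straight line, zero curvature
  straight <- make_arch_centerline(arch_spec(bend_angle_deg = 180))
  expect_equal(measure_arch_angle(straight), 180)
  expect_lt(max(abs(straight$curvature)), 1e-9)
})

test_that("venogram renderer is deterministic and recovers the tube", {
  sp <- arch_spec(diameter = 0.8, bend_angle_deg = 140, arm_length_pre = 2,
                  arm_length_post = 2, bend_radius = 1.5)
  cl <- make_arch_centerline(sp)
  v1 <- render_venogram(cl, 0.8, pixel_spacing = 0.25, noise_sd = 0.05,
                        seed = 3L)
  v2 <- render_venogram(cl, 0.8, pixel_spacing = 0.25, noise_sd = 0.05,
                        seed = 3L)
  expect_identical(v1$frames, v2$frames)
  # noise-free long arch: midpoint threshold recovers the tube; skeleton
  # length close to the path length (skeleton endpoints retract by ~a pixel
  # radius fraction, so a vessel much longer than its diameter is used)
  spL <- arch_spec(diameter = 0.8, bend_angle_deg = 130, arm_length_pre = 5,
                   arm_length_post = 5, bend_radius = 2)
  clL <- make_arch_centerline(spL)
  v0 <- render_venogram(clL, 0.8, pixel_spacing = 0.25, noise_sd = 0,
                        seed = 1L, n_frames = 1L)
  mask <- binarize_and_clean(min_intensity_projection(v0), 0.5)
  sk <- skeletonize_mask(mask)
  path <- extract_centerline(sk, 0.25)
  expect_equal(path_length(path), path_length(clL),
               tolerance = 0.02)
  # canvas too small is refused with the required size
  expect_error(render_venogram(cl, 0.8, canvas_px = c(10, 10)),
               "canvas")
})

test_that("IVUS renderer hits the pullback geometry it was asked for", {
  sp <- arch_spec(diameter = 0.95, bend_angle_deg = 125, arm_length_pre = 2,
                  arm_length_post = 2, bend_radius = 2)
  iv <- render_ivus_stack(sp, frames_per_mm = 30L, image_px = 128L,
                          contour_noise_sd = 0, seed = 1L, lead_in_cm = 1)
  defl <- (180 - 125) * pi / 180
  total_mm <- 10 + (2 + 2 + 2 * defl) * 10
  # one frame per 1/30 mm covering [0, total): a 10 cm pullback gives 3000
  n_expect <- floor(total_mm * 30 - 1e-6) + 1L
  expect_equal(length(iv$contours), n_expect)
  # past the lead-in, unstenosed areas are the circle area pi (0.475)^2
  arch_frames <- which(iv$truth$s_mm > iv$truth$lead_in_mm + 2)
  areas <- vapply(iv$contours[arch_frames], function(ct) ct$area_cm2,
                  numeric(1))
  expect_equal(mean(areas), pi * 0.475^2, tolerance = 0.01)
  # lead-in is distinctly larger (1.5x diameter = 2.25x area)
  lead_frames <- which(iv$truth$s_mm < iv$truth$lead_in_mm - 2)
  expect_equal(mean(vapply(iv$contours[lead_frames],
                           function(ct) ct$area_cm2, numeric(1))),
               2.25 * pi * 0.475^2, tolerance = 0.01)
  # field of view must contain the lumen
  expect_error(render_ivus_stack(sp, image_px = 64L, fov_mm = 8),
               "field of view")
})

test_that("stenosis severity scales the minimum area as constructed", {
  sp <- arch_spec(diameter = 0.95, bend_angle_deg = 125, arm_length_pre = 2,
                  arm_length_post = 2, bend_radius = 2,
                  stenoses = list(list(arclength_fraction = 0.5,
                                       severity = 0.4, extent = 1.5)))
  iv <- render_ivus_stack(sp, frames_per_mm = 10L, image_px = 64L,
                          fov_mm = 20, contour_noise_sd = 0, seed = 1L)
  areas <- iv$truth$area_cm2[iv$truth$s_mm > iv$truth$lead_in_mm]
  expect_equal(min(areas), 0.6 * pi * 0.475^2, tolerance = 0.01)
})

test_that("patient record generator spans the cohort ranges reproducibly", {
  r1 <- gen_patient_records(40, seed = 9L)
  r2 <- gen_patient_records(40, seed = 9L)
  expect_identical(r1, r2)
  expect_true(all(r1$diastolic_velocity_cm_s < r1$systolic_velocity_cm_s))
  expect_true(all(r1$systolic_velocity_cm_s >= 9.4 &
                    r1$systolic_velocity_cm_s <= 66.6))
  expect_true(all(r1$wbv_cP >= 2.68 & r1$wbv_cP <= 4.63))
  expect_true(all(r1$pulse_bpm >= 71 & r1$pulse_bpm <= 101))
  expect_true(all(r1$vein_diameter_cm >= 0.66 & r1$vein_diameter_cm <= 1.1))
  re <- reynolds(u = r1$systolic_velocity_cm_s / 100,
                 L = r1$vein_diameter_cm / 100, eta = r1$wbv_cP * 1e-3)
  expect_true(all(re >= 100 & re <= 2100))
})
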