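# The shared Poiseuille benchmark: straight 9.5 mm tube, mean inlet 5 cm/s,
# eta = 3.45 mPa s (Re ~ 155). Analytic references: centerline velocity
# 2 V, pressure drop 32 eta L V / d^2, wall shear 8 eta V / d.

test_that("discretization reports the expected cell size and cell count", {
  pr <- poiseuille_run()
  expect_equal(pr$dom$h * 1e3, 9.5 / 16, tolerance = 2e-3)
  vol <- mesh_volume(pr$geom$vertices, pr$geom$faces) * 1e-9    # m^3
  expect_equal(length(pr$dom$cell_index) * pr$dom$h^3, vol, tolerance = 0.10)
  broken <- pr$geom
  broken$faces <- broken$faces[-10, ]
  expect_error(discretize(broken), "watertight")
  thin <- suppressWarnings(make_idealized_arch(diameter = 0.2,
                                               bend_angle = 180,
                                               arm_length_pre = 1,
                                               arm_length_post = 1))
  expect_error(discretize(thin, cells_across_diameter = 16L,
                          theta_min = 0.25), NA) # 16 across 2 mm is fine
  expect_error(discretize(pr$geom, cells_across_diameter = 2L), "thinner")
})

test_that("steady tube flow reproduces Poiseuille flow", {
  pr <- poiseuille_run()
  ff <- pr$field
  expect_true(ff$converged)
  uc <- cell_velocity(ff)
  speed <- sqrt(rowSums(uc^2))
  A <- pi * 0.00475^2
  q_in <- flux_through(ff, 0.2)
  q_out <- flux_through(ff, 0.8)
  # mass conservation between sections
  expect_lt(abs(q_out - q_in) / abs(q_in), 0.01)
  # centerline maximum is twice the mean
  expect_equal(max(speed) / (q_in / A), 2.00, tolerance = 0.025)
  # Hagen-Poiseuille pressure drop over the middle 60% of the tube
  L <- 0.6 * pr$dom$s_total
  dp_th <- 32 * 3.45e-3 * L * 0.05 / 0.0095^2
  expect_equal(pressure_drop(ff, 0.2, 0.8), dp_th, tolerance = 0.05)
  # parabolic profile shape
  prof <- velocity_profile(ff, station = 30)
  fit <- 1 - (prof$xi * 0.98)^2
  expect_lt(sqrt(mean((prof$u_norm - fit / max(fit))^2)), 0.05)
  expect_equal(max(prof$u_norm), 1)
  expect_lt(asymmetry_index(prof), 0.01)
})

test_that("wall shear stress matches the analytic tube value and scales with eta", {
  pr <- poiseuille_run()
  wall <- compute_wss(pr$field)
  mid <- wall$s_frac > 0.3 & wall$s_frac < 0.7
  tw_th <- 8 * 3.45e-3 * 0.05 / 0.0095
  expect_equal(mean(wall$tau[mid]), tw_th, tolerance = 0.10)
  wall2 <- compute_wss(pr$field, eta = 2 * 3.45e-3)
  expect_equal(wall2$tau, 2 * wall$tau)
})

test_that("zero inflow gives the rest state at outlet pressure", {
  pr <- poiseuille_run()
  cond0 <- flow_conditions(inlet_waveform("constant", u_max = 0))
  f0 <- solve_steady(pr$dom, pr$props, cond0)
  expect_equal(max(abs(cell_velocity(f0))), 0)
  expect_equal(unique(round(f0$p[pr$dom$ctype[pr$dom$cell_index] == 1L], 6)),
               round(mmhg_to_pa(23), 6))
  expect_equal(max(compute_re_cell(f0)), 0)
  wall0 <- compute_wss(f0)
  expect_equal(max(wall0$tau), 0)
})

test_that("cell Reynolds number follows rho |u| h / eta", {
  pr <- poiseuille_run()
  rc <- compute_re_cell(pr$field)
  uc <- sqrt(rowSums(cell_velocity(pr$field)^2))
  expect_equal(rc, 1060 * uc * pr$dom$h / 3.45e-3)
  # linear in the element size by definition
  expect_equal(compute_re_cell(pr$field,
                               fluid_properties(1060, 2 * 3.45e-3)),
               rc / 2)
})

test_that("solver is deterministic", {
  pr <- poiseuille_run()
  cond <- flow_conditions(inlet_waveform("constant", u_max = 0.05))
  f2 <- solve_steady(pr$dom, pr$props, cond, max_steps = 8000L)
  expect_identical(f2$u, pr$field$u)
  expect_identical(f2$p, pr$field$p)
})

test_that("region maxima are translation invariant in a uniform tube", {
  pr <- poiseuille_run()
  geom_lab <- pr$dom$geom
  # fabricate three equal-length regions along the straight tube
  n <- geom_lab$n_rings
  pr$field$domain$geom$region_label <-
    rep(c("pre-bend", "bend", "post-bend"), length.out = n)[order(seq_len(n))]
  pr$field$domain$geom$region_label <-
    c(rep("pre-bend", floor(n / 3)), rep("bend", floor(n / 3)),
      rep("post-bend", n - 2 * floor(n / 3)))
  rm_ <- region_maxima(pr$field)
  expect_equal(rm_$max_velocity_m_s[2] / rm_$max_velocity_m_s[1], 1,
               tolerance = 0.02)
  expect_equal(rm_$max_velocity_m_s[3] / rm_$max_velocity_m_s[1], 1,
               tolerance = 0.02)
  # reproducible random slice under a fixed seed
  ra <- region_maxima(pr$field, slice_rule = "random", seed = 4L)
  rb <- region_maxima(pr$field, slice_rule = "random", seed = 4L)
  expect_identical(ra, rb)
})

test_that("uniform tube has no recirculation and no large low-WSS patches", {
  pr <- poiseuille_run()
  rc <- detect_recirculation(pr$field)
  expect_false(rc$flag)
  wall <- compute_wss(pr$field)
  lw <- detect_low_wss(wall, pr$dom)
  # WSS in a tube is nearly uniform: percentile-flagged patches are noise
  # (their shear deficit relative to the wall median is a couple of percent,
  # versus ~30% for a genuine bend patch)
  if (nrow(lw)) expect_lt(max(lw$score), 0.05)
  expect_equal(nrow(detect_low_wss(wall, pr$dom, percentile = 0)), 0L)
})

test_that("waveform-driven field export writes VTK files", {
  pr <- poiseuille_run()
  f <- tempfile(fileext = ".vtk")
  write_vtk_field(pr$field, f)
  expect_equal(readLines(f, n = 1), "# vtk DataFile Version 3.0")
  unlink(f)
})
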