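test_that("Reynolds numbers reproduce the measured cohort", {
  t2 <- cephalic_cohort()
  re <- reynolds(u = t2$systolic_velocity_cm_s / 100,
                 L = t2$vein_diameter_cm / 100,
                 eta = t2$wbv_cP * 1e-3)
  expect_equal(re, t2$reynolds)
  # spot values
  expect_equal(reynolds(1060, 0.176, 0.0081, 0.00412), 367)
  expect_equal(reynolds(1060, 0.566, 0.0109, 0.00335), 1952)
  expect_equal(reynolds(1060, 0, 0.0081, 0.00412), 0)
})

test_that("reynolds validates inputs and is linear in u and 1/eta", {
  expect_error(reynolds(1060, 0.1, 0, 3e-3), "positive")
  expect_error(reynolds(1060, 0.1, 0.01, -1), "positive")
  expect_error(reynolds(1060, -0.1, 0.01, 3e-3))
  set.seed(11)
  for (i in 1:20) {
    u <- runif(1, 0.01, 1); L <- runif(1, 0.005, 0.02)
    eta <- runif(1, 2e-3, 5e-3); a <- runif(1, 0.5, 3)
    r0 <- reynolds(1060, u, L, eta, rounded = FALSE)
    expect_equal(reynolds(1060, a * u, L, eta, rounded = FALSE), a * r0)
    expect_equal(reynolds(1060, u, L, eta / a, rounded = FALSE), a * r0)
  }
})

test_that("equivalent diameter matches printed values at printed precision", {
  expect_equal(round(diameter_from_area(0.513), 2), 0.81)
  expect_equal(round(diameter_from_area(0.930), 1), 1.1)
  expect_equal(round(diameter_from_area(0.840), 2), 1.03)
  expect_equal(round(diameter_from_area(0.935), 2), 1.09)
  expect_equal(diameter_from_area(pi / 4), 1.0)
  expect_error(diameter_from_area(0), "positive")
})

test_that("pressure conversion uses 133.322 Pa per mmHg", {
  expect_equal(mmhg_to_pa(23), 3066.406)
  expect_equal(mmhg_to_pa(20), 2666.44)
  expect_equal(mmhg_to_pa(0), 0)
})

test_that("cohort summary reproduces the reported 3- and 12-month statistics", {
  cs <- cohort_summary(cephalic_cohort())
  tp <- cs$by_timepoint
  m3 <- tp[tp$timepoint == "3mo", ]
  m12 <- tp[tp$timepoint == "12mo", ]
  expect_equal(round(m3$mean_diameter_cm, 2), 0.85)
  expect_equal(round(m3$mean_arch_angle_deg), 137)
  expect_equal(round(m3$mean_velocity_cm_s, 1), 45.2)
  expect_equal(round(m3$mean_re), 1239)
  expect_equal(round(m12$mean_diameter_cm, 2), 0.87)
  expect_equal(round(m12$mean_arch_angle_deg), 125)
  expect_equal(round(m12$mean_velocity_cm_s, 1), 28.9)
  expect_equal(round(m12$mean_re), 740)
  ra <- cs$re_avg_by_patient
  expect_equal(round(ra$re_avg[ra$patient_id == "P93"]), 339)
  expect_equal(round(ra$re_avg[ra$patient_id == "P122"]), 1566)
  # reported spreads are sample SDs
  expect_equal(round(m3$sd_diameter_cm, 2), 0.16)
  expect_equal(round(m12$sd_diameter_cm, 1), 0.2)
})

test_that("single-record timepoints report zero SD with a flag", {
  one <- cephalic_cohort()[1, ]
  cs <- cohort_summary(one)
  expect_equal(cs$by_timepoint$sd_re, 0)
  expect_false(cs$by_timepoint$sd_defined)
})
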